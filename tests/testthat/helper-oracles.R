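# Independent oracles. These deliberately avoid the package's C++ engine:
# the net benefit is recomputed by a naive double loop over subjects using
# the scalar R scoring functions, and small-sample permutation p-values by
# exhaustive enumeration of equal-size label splits.

naive_net_benefit <- function(rates, specs, mode = "prioritized") {
  trt <- rates[rates$arm == "treated", , drop = FALSE]
  ctl <- rates[rates$arm == "control", , drop = FALSE]
  doms <- specs$name
  scorer <- if (mode == "prioritized") score_pair_prioritized else
    score_pair_nonprioritized
  scores <- c()
  for (i in seq_len(nrow(trt)))
    for (j in seq_len(nrow(ctl)))
      scores <- c(scores, scorer(as.numeric(trt[i, doms]),
                                 as.numeric(ctl[j, doms]), specs)$score)
  list(delta = mean(scores),
       wins = sum(pmax(scores, 0)),
       losses = sum(pmax(-scores, 0)),
       neutral = sum(scores == 0),
       n_pairs = length(scores))
}

# Exact two-sided permutation p over all C(n, n_t) label splits (the
# observed split is one of them; no add-one correction in the exact case).
exact_perm_p <- function(rates, specs, mode = "prioritized") {
  n <- nrow(rates)
  n_t <- sum(rates$arm == "treated")
  obs <- naive_net_benefit(rates, specs, mode)$delta
  splits <- utils::combn(n, n_t)
  deltas <- apply(splits, 2, function(t_idx) {
    relabeled <- rates
    relabeled$arm <- "control"
    relabeled$arm[t_idx] <- "treated"
    class(relabeled) <- class(rates)
    attr(relabeled, "domains") <- attr(rates, "domains")
    naive_net_benefit(relabeled, specs, mode)$delta
  })
  list(p = mean(abs(deltas) >= abs(obs) - 1e-12), deltas = deltas,
       delta_obs = obs)
}

# Random small rate table for property tests.
random_rate_table <- function(n_t, n_c, K, scale = 1) {
  n <- n_t + n_c
  rates <- as.data.frame(matrix(stats::rnorm(n * K, sd = scale), n, K))
  names(rates) <- paste0("d", seq_len(K))
  rate_table(seq_len(n), rep(c("treated", "control"), c(n_t, n_c)), rates)
}

random_specs <- function(K, max_threshold = 0.5) {
  outcome_specs(paste0("d", seq_len(K)),
                direction = sample(c(-1L, 1L), K, replace = TRUE),
                threshold = stats::runif(K, 0, max_threshold),
                priority = sample(K))
}

swap_arms <- function(rates) {
  rates$arm <- ifelse(rates$arm == "treated", "control", "treated")
  rates
}

# Small deterministic generator config (3 domains) for fast simulator and
# power tests; slope shifts and variances chosen so effects are large.
tiny_gen <- function(...) {
  generator_config(domains = c("a", "b", "c"),
                   baseline_mean = c(10, 0, 5),
                   slope_control = c(1, 0.5, -0.2),
                   slope_treated = c(3, 1.5, -1.2),
                   direction = c(1L, 1L, -1L),
                   sd_baseline_re = c(2, 1, 1),
                   std_effect = c(1, 1, 1), ...)
}
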