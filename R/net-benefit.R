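## Per-outcome all-vs-all score matrices: entry (i, j) is the
## single-outcome score of subject i as treated vs subject j as control.
## Built once per analysis; a win requires the directed difference to
## STRICTLY exceed the threshold, so a boundary difference is neutral.
score_matrices <- function(x, specs) {
  lapply(seq_len(nrow(specs)), function(k) {
    d <- specs$direction[k] * outer(x[, k], x[, k], "-")
    m <- (d > specs$threshold[k]) - (d < -specs$threshold[k])
    storage.mode(m) <- "integer"
    m
  })
}

#' Net treatment benefit from generalized pairwise comparisons
#'
#' Compares every treated subject with every control subject. In
#' prioritized mode each pair is scored by the highest-priority outcome
#' with an informative (non-neutral) comparison; in non-prioritized mode
#' each pair's score is the weighted mean of its per-outcome scores. The
#' net benefit is the mean pairwise score,
#' \eqn{\Delta = (\mathrm{wins} - \mathrm{losses}) / n_{\mathrm{pairs}}},
#' the net probability that a random treated subject does better than a
#' random control subject.
#'
#' @param rates a [rate_table] with at least one subject per arm.
#' @param specs an [outcome_specs] whose names match the rate table's
#'   domain columns.
#' @param mode `"prioritized"` or `"nonprioritized"`.
#' @return An object of class `"net_benefit"`: a list with `delta`,
#'   `n_pairs`, `wins`, `losses`, `neutral` (fractional in non-prioritized
#'   mode), `mode`, `specs`, and in prioritized mode `deciding`, the count
#'   of pairs decided at each priority level (last element = pairs neutral
#'   on all outcomes).
#' @examples
#' rt <- rate_table(1:6, rep(c("treated", "control"), each = 3),
#'                  data.frame(score = c(3, 2, 1, 2, 1, 0)))
#' net_benefit(rt, outcome_specs("score"))   # delta = 5/9
#' @export
net_benefit <- function(rates, specs,
                        mode = c("prioritized", "nonprioritized")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rates, "rate_table"), inherits(specs, "outcome_specs"))
  domains <- rate_domains(rates)
  if (!all(specs$name %in% domains))
    stop("outcome(s) not present in rate table: ",
         paste(setdiff(specs$name, domains), collapse = ", "))
  tidx <- which(rates$arm == "treated")
  cidx <- which(rates$arm == "control")
  if (length(tidx) == 0L || length(cidx) == 0L)
    stop("both arms must be non-empty")
  prioritized <- mode == "prioritized"
  sp <- if (prioritized) specs_by_priority(specs) else specs
  x <- as.matrix(rates[, sp$name, drop = FALSE])
  S <- score_matrices(x, sp)
  r <- cpp_gpc_eval(S, tidx, cidx, prioritized, normalized_weights(sp))
  out <- list(delta = r$delta, n_pairs = length(tidx) * length(cidx),
              wins = r$wins, losses = r$losses, neutral = r$neutral,
              mode = mode, specs = specs)
  if (prioritized) {
    deciding <- r$deciding
    names(deciding) <- c(sp$name, "all_neutral")
    out$deciding <- deciding
  }
  class(out) <- "net_benefit"
  out
}

#' @export
print.net_benefit <- function(x, ...) {
  cat(sprintf("GPC net benefit (%s): delta = %.4f\n", x$mode, x$delta))
  cat(sprintf("  pairs: %d  (wins %.3f, losses %.3f, neutral %.3f)\n",
              x$n_pairs, x$wins, x$losses, x$neutral))
  if (!is.null(x$deciding)) {
    cat("  pairs decided per priority level:\n")
    print(x$deciding)
  }
  invisible(x)
}

#' Permutation test for the net benefit
#'
#' Tests the null hypothesis of no treatment effect by randomly
#' reassigning arm labels (preserving arm sizes), recomputing the net
#' benefit for each relabelling, and comparing. The two-sided p-value uses
#' the add-one correction
#' \eqn{p = (1 + \#\{|\Delta_b| \ge |\Delta_{obs}|\}) / (1 + B)}, so
#' \eqn{p \ge 1/(1+B)} always.
#'
#' @inheritParams net_benefit
#' @param B number of label permutations (default 1000).
#' @param seed optional integer seed; identical inputs and seed give an
#'   identical p-value.
#' @return An object of class `"gpc_permutation"`: list with `delta_obs`,
#'   `p_value`, `B`, `seed`, `perm_deltas` (the permuted statistics) and
#'   the observed `net_benefit` object.
#' @export
permutation_test <- function(rates, specs,
                             mode = c("prioritized", "nonprioritized"),
                             B = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer")
  n <- nrow(rates)
  if (n < 2L) stop("at least two subjects are required")
  obs <- net_benefit(rates, specs, mode)
  if (!is.null(seed)) set.seed(seed)
  perms <- t(replicate(B, sample.int(n)))
  if (B == 1L) perms <- matrix(perms, nrow = 1L)
  p <- perm_pvalue_from_matrix(rates, specs, mode, perms, obs$delta)
  structure(list(delta_obs = obs$delta, p_value = p$p_value, B = B,
                 seed = seed, perm_deltas = p$deltas, net_benefit = obs),
            class = "gpc_permutation")
}

## internal: permutation p-value given a pre-drawn B x n permutation
## matrix (shared across modes/thresholds for common random numbers)
perm_pvalue_from_matrix <- function(rates, specs, mode, perms, delta_obs) {
  prioritized <- mode == "prioritized"
  sp <- if (prioritized) specs_by_priority(specs) else specs
  x <- as.matrix(rates[, sp$name, drop = FALSE])
  S <- score_matrices(x, sp)
  ## relabel so the first n_t permuted positions are "treated"
  ord <- order(rates$arm != "treated")   # treated rows first
  S <- lapply(S, function(m) m[ord, ord, drop = FALSE])
  n_t <- sum(rates$arm == "treated")
  deltas <- cpp_perm_deltas(S, perms, n_t, prioritized,
                            normalized_weights(sp))
  list(p_value = (1 + sum(abs(deltas) >= abs(delta_obs))) /
         (1 + nrow(perms)),
       deltas = deltas)
}

#' @export
print.gpc_permutation <- function(x, ...) {
  cat(sprintf("GPC permutation test: delta = %.4f, p = %.4g (B = %d)\n",
              x$delta_obs, x$p_value, x$B))
  invisible(x)
}

#' Export a single GPC analysis as a JSON report
#'
#' Writes mode, the outcome specification, net-benefit components, the
#' permutation p-value, B and seed to a JSON file.
#'
#' @param test a `gpc_permutation` object from [permutation_test()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gpc_report <- function(test, path) {
  stopifnot(inherits(test, "gpc_permutation"))
  nb <- test$net_benefit
  rep <- list(mode = nb$mode,
              outcomes = as.data.frame(nb$specs),
              delta = nb$delta, n_pairs = nb$n_pairs,
              wins = nb$wins, losses = nb$losses, neutral = nb$neutral,
              deciding = as.list(nb$deciding),
              p_value = test$p_value, n_permutations = test$B,
              seed = test$seed)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
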