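#' Configuration of the five-domain longitudinal trajectory generator
#'
#' Builds the stated world of the simulator: a linear-plus-quadratic
#' mixed-effects trajectory per domain,
#' \deqn{Y_{idj} = \mu_d + s_d t_j + q_d t_j^2 + b_{0,id} + b_{1,id} t_j +
#'   \epsilon_{idj},}
#' with time in years, subject-level random intercepts and slopes jointly
#' multivariate normal across domains (exchangeable cross-domain
#' correlation), and independent visit-level noise. The treated arm
#' differs from the control arm only through the fixed slope
#' \eqn{s_d}.
#'
#' Default fixed effects reproduce the natural-history summaries of an
#' MPS IIIA (Sanfilippo A) cohort: baseline centers 63, 30.5, 58, 4, 75
#' and control-arm per-year rates of change 1.31, 0.10, 0.28, -0.01,
#' -0.21 for expressive language, daily living skills, gross motor, sleep
#' and pain; treated-arm rates 3.53, 0.42, 0.94, -0.47, 0.50. Because the
#' fitted variance components of the source cohort are unpublished, the
#' default variance scales are calibrated: the slope shift
#' `|slope_treated - slope_control|`, expressed in SDs of the per-subject
#' rate-of-change distribution, equals `std_effect` (default 1.0, 0.45,
#' 0.6, 0.5, 0.5 — expressive language dominant, the others moderate),
#' and the visit-level residual contributes half of the rate variance.
#'
#' @param domains character vector of K domain labels.
#' @param baseline_mean per-domain baseline fixed effect \eqn{\mu_d}.
#' @param slope_control,slope_treated per-domain fixed slope per year.
#' @param direction per-domain direction of benefit (+1 larger is better);
#'   carried along so analyses can build matching [outcome_specs].
#' @param quad_coef per-domain quadratic coefficient per year squared.
#' @param std_effect standardized slope-shift targets used only to derive
#'   the default `sd_slope_re`/`sd_residual`; ignored when both are given.
#' @param sd_baseline_re per-domain SD of the random intercept.
#' @param sd_slope_re per-domain SD of the random slope (per year).
#' @param sd_residual per-domain SD of the visit-level noise.
#' @param cross_domain_corr exchangeable correlation in `[0, 1)` between
#'   random effects of the same kind across domains.
#' @param visit_months assessment schedule in months; must contain 0 and
#'   24 (the rate of change uses both endpoints).
#' @param clip_range optional K x 2 matrix of instrument bounds for
#'   display clipping by [generate_arm()]'s `clip` argument; scores are
#'   NOT clipped by default.
#' @return A list of class `"generator_config"` with all parameters
#'   resolved; construction fails if the implied random-effect covariance
#'   matrix is not positive semi-definite.
#' @export
generator_config <- function(domains = c("expressive_language",
                                         "daily_living_skills",
                                         "gross_motor", "sleep", "pain"),
                             baseline_mean = c(63, 30.5, 58, 4, 75),
                             slope_control = c(1.31, 0.10, 0.28, -0.01, -0.21),
                             slope_treated = c(3.53, 0.42, 0.94, -0.47, 0.50),
                             direction = c(1L, 1L, 1L, -1L, 1L),
                             quad_coef = 0,
                             std_effect = c(1.0, 0.45, 0.6, 0.5, 0.5),
                             sd_baseline_re = c(35, 4.75, 18.5, 2.5, 18.75),
                             sd_slope_re = NULL,
                             sd_residual = NULL,
                             cross_domain_corr = 0.3,
                             visit_months = c(0, 6, 12, 18, 24),
                             clip_range = NULL) {
  K <- length(domains)
  if (K < 1L || anyDuplicated(domains)) stop("domains must be unique labels")
  rec <- function(x, what) {
    x <- as.numeric(rep_len(x, K))
    if (any(!is.finite(x))) stop(what, " must be finite")
    x
  }
  baseline_mean <- rec(baseline_mean, "baseline_mean")
  slope_control <- rec(slope_control, "slope_control")
  slope_treated <- rec(slope_treated, "slope_treated")
  quad_coef <- rec(quad_coef, "quad_coef")
  direction <- as.integer(rep_len(direction, K))
  if (!all(direction %in% c(-1L, 1L))) stop("direction must be +1 or -1")
  std_effect <- rec(std_effect, "std_effect")
  sd_baseline_re <- rec(sd_baseline_re, "sd_baseline_re")
  if (is.null(sd_slope_re) || is.null(sd_residual)) {
    ## calibrate total rate SD so the standardized slope shift equals
    ## std_effect, then split the variance 50/50 between random slope and
    ## residual (rate variance = sd_slope^2 + sd_residual^2 / 2)
    if (any(std_effect <= 0)) stop("std_effect must be positive")
    shift <- abs(slope_treated - slope_control)
    if (any(shift == 0))
      stop("default variance calibration needs a nonzero slope shift in ",
           "every domain; supply sd_slope_re and sd_residual explicitly")
    rate_sd_target <- shift / std_effect
    if (is.null(sd_slope_re)) sd_slope_re <- rate_sd_target / sqrt(2)
    if (is.null(sd_residual)) sd_residual <- rate_sd_target
  }
  sd_slope_re <- rec(sd_slope_re, "sd_slope_re")
  sd_residual <- rec(sd_residual, "sd_residual")
  if (any(c(sd_baseline_re, sd_slope_re, sd_residual) < 0))
    stop("all SDs must be >= 0")
  if (!is.finite(cross_domain_corr) || cross_domain_corr < 0 ||
      cross_domain_corr >= 1)
    stop("cross_domain_corr must lie in [0, 1)")
  visit_months <- sort(unique(as.numeric(visit_months)))
  if (!all(c(0, 24) %in% visit_months))
    stop("visit_months must include 0 and 24 (rate endpoints)")
  if (!is.null(clip_range)) {
    clip_range <- matrix(as.numeric(clip_range), nrow = K, ncol = 2)
    if (any(clip_range[, 1] > clip_range[, 2]))
      stop("clip_range rows must be (lower, upper)")
  }
  cfg <- structure(list(domains = as.character(domains),
                        baseline_mean = baseline_mean,
                        slope_control = slope_control,
                        slope_treated = slope_treated,
                        direction = direction,
                        quad_coef = quad_coef,
                        std_effect = std_effect,
                        sd_baseline_re = sd_baseline_re,
                        sd_slope_re = sd_slope_re,
                        sd_residual = sd_residual,
                        cross_domain_corr = cross_domain_corr,
                        visit_months = visit_months,
                        clip_range = clip_range),
                   class = "generator_config")
  Sigma <- re_covariance(cfg)   # errors here if not PSD
  attr(cfg, "re_covariance") <- Sigma
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Longitudinal generator over", length(x$domains), "domains,",
      "visits (months):", paste(x$visit_months, collapse = ", "), "\n")
  tab <- data.frame(domain = x$domains, baseline = x$baseline_mean,
                    slope_control = x$slope_control,
                    slope_treated = x$slope_treated,
                    direction = x$direction,
                    rate_sd = rate_sd(x))
  print(tab, row.names = FALSE)
  cat("cross-domain random-effect correlation:", x$cross_domain_corr, "\n")
  invisible(x)
}

## Joint covariance of the 2K random effects (K intercepts then K slopes).
## Intercepts share an exchangeable correlation across domains, as do
## slopes; intercepts and slopes are independent of each other.
re_covariance <- function(cfg) {
  K <- length(cfg$domains)
  rho <- cfg$cross_domain_corr
  exch <- matrix(rho, K, K); diag(exch) <- 1
  block <- function(sds) outer(sds, sds) * exch
  Sigma <- matrix(0, 2 * K, 2 * K)
  Sigma[seq_len(K), seq_len(K)] <- block(cfg$sd_baseline_re)
  Sigma[K + seq_len(K), K + seq_len(K)] <- block(cfg$sd_slope_re)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("random-effect covariance matrix is not positive semi-definite")
  Sigma
}

#' Simulate one arm of longitudinal five-domain trajectories
#'
#' Draws `n` subjects from the mixed-effects model of `config`, using the
#' control or treated fixed slopes, and returns the complete grid of
#' scores at every visit for every domain.
#'
#' @param config a [generator_config].
#' @param arm `"control"` or `"treated"` (selects the fixed slope).
#' @param n number of subjects (`n = 0` gives an empty dataset).
#' @param seed optional integer seed for reproducibility.
#' @param subject_prefix prefix for generated subject identifiers.
#' @param clip if `TRUE` and the config has a `clip_range`, truncate
#'   scores to the instrument bounds (display only; rates are normally
#'   derived from unclipped scores).
#' @return A long data frame of class `"longitudinal_dataset"`: columns
#'   `subject_id`, `arm`, `visit_month`, `domain`, `score`.
#' @export
generate_arm <- function(config, arm = c("control", "treated"), n,
                         seed = NULL, subject_prefix = arm, clip = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  arm <- match.arg(arm)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a nonnegative integer")
  K <- length(config$domains)
  t_years <- config$visit_months / 12
  J <- length(t_years)
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(subject_id = character(), arm = character(),
                      visit_month = numeric(), domain = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n == 0L) {
    class(empty) <- c("longitudinal_dataset", "data.frame")
    return(empty)
  }
  slope <- if (arm == "treated") config$slope_treated else
    config$slope_control
  Sigma <- attr(config, "re_covariance")
  if (is.null(Sigma)) Sigma <- re_covariance(config)
  b <- MASS::mvrnorm(n, mu = rep(0, 2 * K), Sigma = Sigma)
  if (n == 1L) b <- matrix(b, nrow = 1L)
  b0 <- b[, seq_len(K), drop = FALSE]
  b1 <- b[, K + seq_len(K), drop = FALSE]
  eps <- array(stats::rnorm(n * J * K), dim = c(n, J, K))
  ids <- sprintf("%s_%04d", subject_prefix, seq_len(n))
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    mu <- config$baseline_mean[k] + slope[k] * t_years +
      config$quad_coef[k] * t_years^2                       # length J
    y <- matrix(mu, n, J, byrow = TRUE) +
      b0[, k] + outer(b1[, k], t_years) +
      eps[, , k] * config$sd_residual[k]
    if (clip && !is.null(config$clip_range))
      y <- pmin(pmax(y, config$clip_range[k, 1]), config$clip_range[k, 2])
    rows[[k]] <- data.frame(subject_id = rep(ids, times = J),
                            arm = arm,
                            visit_month = rep(config$visit_months, each = n),
                            domain = config$domains[k],
                            score = as.vector(y),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("longitudinal_dataset", "data.frame")
  out
}

#' Simulate a two-arm trial
#'
#' Convenience wrapper generating a control arm and a treated arm (or,
#' under the null, a second arm with control-arm slopes) from one seed.
#'
#' @inheritParams generate_arm
#' @param n_per_arm subjects per arm.
#' @param null if `TRUE`, the "treated" arm is generated with the control
#'   slopes (no treatment effect) — used for type-I-error calibration.
#' @return a `longitudinal_dataset` holding both arms.
#' @export
generate_trial <- function(config, n_per_arm, seed = NULL, null = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ctrl <- generate_arm(config, "control", n_per_arm)
  trt_cfg <- config
  if (null) trt_cfg$slope_treated <- config$slope_control
  trt <- generate_arm(trt_cfg, "treated", n_per_arm)
  out <- rbind(trt, ctrl)
  class(out) <- c("longitudinal_dataset", "data.frame")
  out
}

#' Derive per-subject rates of change from a longitudinal dataset
#'
#' The rate of change is the endpoint the pairwise analysis compares:
#' (score at month 24 minus score at month 0) divided by 2 years.
#' Intermediate visits are carried in the dataset but not used.
#'
#' @param data a `longitudinal_dataset` with complete month-0 and
#'   month-24 scores for every subject and domain.
#' @return a [rate_table] with one column per domain, in units per year.
#' @export
derive_rates <- function(data) {
  need <- c("subject_id", "arm", "visit_month", "domain", "score")
  if (!all(need %in% names(data)))
    stop("dataset must have columns ", paste(need, collapse = ", "))
  ends <- data[data$visit_month %in% c(0, 24), need]
  domains <- unique(data$domain)
  ## every subject x domain must contribute exactly both endpoints
  cnt <- table(ends$subject_id, ends$domain)
  bad <- which(cnt != 2, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("missing endpoint visit for subject ", rownames(cnt)[bad[1, 1]],
         ", domain ", colnames(cnt)[bad[1, 2]])
  y0 <- ends[ends$visit_month == 0, ]
  y24 <- ends[ends$visit_month == 24, ]
  m0 <- tapply(y0$score, list(y0$subject_id, y0$domain), identity)
  m24 <- tapply(y24$score, list(y24$subject_id, y24$domain), identity)
  rate <- (m24 - m0)[, domains, drop = FALSE] / 2
  arm_of <- tapply(data$arm, data$subject_id, function(a) a[1])
  ids <- rownames(rate)
  rate_table(ids, as.character(arm_of[ids]),
             as.data.frame(rate, stringsAsFactors = FALSE))
}

#' Standard deviation of the per-subject rate of change
#'
#' Under the generator's model the rate of change for one subject is
#' \eqn{s_d + 2 q_d + b_{1,id} + (\epsilon_{24} - \epsilon_0)/2}, so its
#' SD is analytically
#' \eqn{\sqrt{\sigma_{b_1,d}^2 + \sigma_{\epsilon,d}^2 / 2}}. This is the
#' scale on which thresholds of clinical relevance are expressed
#' (threshold = fraction x rate SD). An empirical mode simulates a large
#' pilot control arm and must agree with the analytic value within Monte
#' Carlo error.
#'
#' @param config a [generator_config].
#' @param method `"analytic"` (closed form) or `"empirical"` (pilot
#'   simulation).
#' @param n_pilot pilot-arm size for the empirical mode.
#' @param seed seed for the empirical mode.
#' @return named numeric vector of per-domain rate SDs.
#' @export
rate_sd <- function(config, method = c("analytic", "empirical"),
                    n_pilot = 100000L, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  method <- match.arg(method)
  out <- switch(method,
    analytic = sqrt(config$sd_slope_re^2 + config$sd_residual^2 / 2),
    empirical = {
      pilot <- generate_arm(config, "control", n_pilot, seed = seed)
      apply(rate_matrix(derive_rates(pilot))[, config$domains, drop = FALSE],
            2, stats::sd)
    })
  stats::setNames(as.numeric(out), config$domains)
}

#' Outcome specification matching a generator configuration
#'
#' Builds the [outcome_specs] that analyze data from `config`: same domain
#' order, the config's directions of benefit, and per-domain thresholds
#' set to `threshold_fraction` times the analytic rate SD.
#'
#' @param config a [generator_config].
#' @param threshold_fraction scalar fraction of the rate SD.
#' @param priority_order integer permutation: outcome indices in
#'   decreasing priority (default the config's domain order).
#' @return an `outcome_specs` object.
#' @export
specs_from_config <- function(config, threshold_fraction = 0,
                              priority_order = seq_along(config$domains)) {
  if (!is.finite(threshold_fraction) || threshold_fraction < 0)
    stop("threshold_fraction must be >= 0")
  sp <- outcome_specs(config$domains, direction = config$direction,
                      threshold = threshold_fraction * rate_sd(config))
  set_priority_order(sp, priority_order)
}

#' Read / write longitudinal datasets as long-format CSV
#'
#' @param data a `longitudinal_dataset`.
#' @param path file path.
#' @return `read_longitudinal()` a `longitudinal_dataset`;
#'   `write_longitudinal()` the path, invisibly.
#' @export
write_longitudinal <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_longitudinal
#' @export
read_longitudinal <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "arm", "visit_month", "domain", "score")
  if (!all(need %in% names(d)))
    stop("longitudinal CSV must have columns ", paste(need, collapse = ", "))
  d$subject_id <- as.character(d$subject_id)
  class(d) <- c("longitudinal_dataset", "data.frame")
  d
}
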