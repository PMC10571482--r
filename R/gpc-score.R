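#' Score one treated-vs-control comparison on a single outcome
#'
#' The elementary generalized-pairwise-comparisons operation: the pair is a
#' win (+1) for treatment if the difference, taken in the direction of
#' benefit, strictly exceeds the threshold of clinical relevance; a loss
#' (-1) if the reverse difference strictly exceeds it; neutral (0)
#' otherwise. A difference exactly equal to the threshold is neutral.
#'
#' @param x_t outcome value of the treated subject.
#' @param x_c outcome value of the control subject.
#' @param direction `+1` if larger is better, `-1` if smaller is better.
#' @param threshold nonnegative threshold of clinical relevance.
#' @return `-1L`, `0L` or `1L`.
#' @examples
#' score_single(3.53, 1.31)                      # win
#' score_single(-0.47, -0.01, direction = -1)    # win on a "smaller is
#'                                               # better" outcome (sleep)
#' score_single(2, 1, threshold = 1)             # boundary: neutral
#' @export
score_single <- function(x_t, x_c, direction = 1L, threshold = 0) {
  if (!is.finite(x_t) || !is.finite(x_c))
    stop("non-finite outcome value; missing data are not supported")
  if (!is.finite(threshold) || threshold < 0)
    stop("threshold must be finite and >= 0")
  if (!direction %in% c(-1L, 1L)) stop("direction must be +1 or -1")
  d <- direction * (x_t - x_c)
  if (d > threshold) 1L else if (-d > threshold) -1L else 0L
}

#' Score a pair of multi-domain outcome vectors hierarchically
#'
#' Walks the outcomes in priority order and returns the first informative
#' (non-neutral) single-outcome score together with the index of the
#' outcome that decided the pair. Outcomes lower in the hierarchy are only
#' consulted when every higher-priority comparison is neutral.
#'
#' @param v_t,v_c numeric vectors of length `K`, the treated and control
#'   subject's values per outcome, in the order of `specs`.
#' @param specs an [outcome_specs] object.
#' @return A list of class `"pair_score"` with elements `score`
#'   (`-1`, `0`, or `+1`) and `deciding_outcome` (index into `specs`, or
#'   `NA` when all comparisons are neutral).
#' @export
score_pair_prioritized <- function(v_t, v_c, specs) {
  stopifnot(inherits(specs, "outcome_specs"))
  K <- nrow(specs)
  if (K < 1L) stop("empty outcome specification")
  if (length(v_t) != K || length(v_c) != K)
    stop("outcome vectors must have length ", K)
  ord <- order(specs$priority)
  for (k in ord) {
    s <- score_single(v_t[k], v_c[k], specs$direction[k], specs$threshold[k])
    if (s != 0L)
      return(structure(list(score = s, deciding_outcome = k),
                       class = "pair_score"))
  }
  structure(list(score = 0L, deciding_outcome = NA_integer_),
            class = "pair_score")
}

#' Score a pair of multi-domain outcome vectors by weighted averaging
#'
#' The non-prioritized pairwise score: the weighted mean of the `K`
#' per-outcome win/loss/neutral scores, weights normalized to sum to 1.
#' With equal weights this is `(wins - losses) / K` over the outcomes.
#'
#' @inheritParams score_pair_prioritized
#' @return A list of class `"pair_score"` with `score` in `[-1, 1]` and
#'   `deciding_outcome = NA` (no single outcome decides the pair).
#' @export
score_pair_nonprioritized <- function(v_t, v_c, specs) {
  stopifnot(inherits(specs, "outcome_specs"))
  K <- nrow(specs)
  if (length(v_t) != K || length(v_c) != K)
    stop("outcome vectors must have length ", K)
  w <- normalized_weights(specs)
  s <- vapply(seq_len(K), function(k)
    score_single(v_t[k], v_c[k], specs$direction[k], specs$threshold[k]),
    integer(1))
  structure(list(score = sum(w * s), deciding_outcome = NA_integer_),
            class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat("pairwise score:", format(x$score),
      if (!is.na(x$deciding_outcome))
        paste0("(decided by outcome ", x$deciding_outcome, ")")
      else "(no deciding outcome)", "\n")
  invisible(x)
}
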