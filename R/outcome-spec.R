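#' Define the outcomes entering a pairwise-comparison analysis
#'
#' An outcome specification is the analysis contract for one domain: the
#' direction of benefit, the threshold of clinical relevance below which a
#' pairwise difference is uninformative, and either a priority rank
#' (hierarchical analysis) or a weight (averaged analysis).
#'
#' @param name character vector of domain labels (must be unique).
#' @param direction integer vector, `+1` if larger values are better, `-1`
#'   if smaller values are better. Recycled to length `K`.
#' @param threshold nonnegative numeric vector of thresholds of clinical
#'   relevance, in the outcome's own units. A pairwise difference whose
#'   magnitude does not exceed the threshold (strictly) is scored neutral.
#'   Recycled to length `K`.
#' @param priority integer vector, a permutation of `1..K` giving the
#'   hierarchy for prioritized analyses (1 = highest priority). Defaults to
#'   the order of `name`.
#' @param weight positive numeric vector of weights for non-prioritized
#'   analyses; normalized to sum to 1 at scoring time. Defaults to equal
#'   weights.
#'
#' @return A data frame of class `"outcome_specs"` with columns `name`,
#'   `direction`, `threshold`, `priority`, `weight`, ordered as given (not
#'   by priority).
#' @examples
#' outcome_specs(c("language", "sleep"), direction = c(1, -1))
#' @export
outcome_specs <- function(name, direction = 1L, threshold = 0,
                          priority = seq_along(name), weight = NULL) {
  if (length(name) < 1L) stop("at least one outcome is required")
  name <- as.character(name)
  if (anyDuplicated(name)) stop("outcome names must be unique")
  K <- length(name)
  direction <- as.integer(rep_len(direction, K))
  threshold <- as.numeric(rep_len(threshold, K))
  if (!all(direction %in% c(-1L, 1L)))
    stop("direction must be +1 or -1 for every outcome")
  if (any(!is.finite(threshold)) || any(threshold < 0))
    stop("threshold must be finite and >= 0 for every outcome")
  priority <- as.integer(priority)
  if (length(priority) != K || !setequal(priority, seq_len(K)))
    stop("priority must be a permutation of 1..", K)
  if (is.null(weight)) weight <- rep(1 / K, K)
  weight <- as.numeric(rep_len(weight, K))
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weights must be finite and positive")
  out <- data.frame(name = name, direction = direction,
                    threshold = threshold, priority = priority,
                    weight = weight, stringsAsFactors = FALSE)
  class(out) <- c("outcome_specs", "data.frame")
  out
}

#' @export
print.outcome_specs <- function(x, ...) {
  cat("Outcome specifications (", nrow(x), " domain",
      if (nrow(x) > 1) "s", "):\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

## internal: validate and return specs reordered by priority (1 first)
specs_by_priority <- function(specs) {
  stopifnot(inherits(specs, "outcome_specs"))
  specs[order(specs$priority), , drop = FALSE]
}

## internal: normalized weight vector in the specs' own order
normalized_weights <- function(specs) {
  w <- specs$weight
  w / sum(w)
}

#' Reorder outcome priorities
#'
#' Returns a copy of `specs` whose priority column encodes the given
#' ordering: the first element of `order` names the index (in `specs`) of
#' the highest-priority outcome, and so on. Weights and thresholds are
#' untouched. Used by priority-order sensitivity analyses.
#'
#' @param specs an [outcome_specs] object.
#' @param order integer permutation of `1..K`, outcome indices in
#'   decreasing priority.
#' @return an `outcome_specs` object.
#' @export
set_priority_order <- function(specs, order) {
  stopifnot(inherits(specs, "outcome_specs"))
  K <- nrow(specs)
  order <- as.integer(order)
  if (length(order) != K || !setequal(order, seq_len(K)))
    stop("order must be a permutation of 1..", K)
  specs$priority[order] <- seq_len(K)
  specs
}
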