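#' Construct a per-subject rate-of-change table
#'
#' The rate table is the quantity generalized pairwise comparisons operate
#' on: one row per subject, with the arm label and one column per domain
#' holding that subject's per-year rate of change. Rates must be complete
#' (no missing values) — the analysis assumes full follow-up.
#'
#' @param subject_id vector of unique subject identifiers.
#' @param arm character vector of arm labels, `"treated"` or `"control"`.
#' @param rates numeric matrix or data frame, one row per subject and one
#'   named column per domain.
#' @return A data frame of class `"rate_table"` with columns `subject_id`,
#'   `arm`, then the domain columns; attribute `domains` holds the domain
#'   names.
#' @export
rate_table <- function(subject_id, arm, rates) {
  rates <- as.data.frame(rates)
  n <- nrow(rates)
  if (length(subject_id) != n || length(arm) != n)
    stop("subject_id, arm and rates must describe the same subjects")
  if (anyDuplicated(subject_id)) stop("subject_id values must be unique")
  arm <- as.character(arm)
  if (!all(arm %in% c("treated", "control")))
    stop("arm must be 'treated' or 'control'")
  if (!all(vapply(rates, is.numeric, logical(1))))
    stop("all rate columns must be numeric")
  if (anyNA(rates) || !all(vapply(rates, function(x) all(is.finite(x)),
                                  logical(1))))
    stop("rates must be complete and finite; missing data are not supported")
  out <- data.frame(subject_id = as.character(subject_id), arm = arm,
                    rates, stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "domains") <- names(rates)
  class(out) <- c("rate_table", "data.frame")
  out
}

rate_domains <- function(rates) {
  d <- attr(rates, "domains")
  if (is.null(d)) d <- setdiff(names(rates), c("subject_id", "arm"))
  d
}

rate_matrix <- function(rates) {
  as.matrix(rates[, rate_domains(rates), drop = FALSE])
}

#' Read / write per-subject rates as long-format CSV
#'
#' The on-disk exchange format is long: columns `subject_id`, `arm`,
#' `domain`, `rate`, one row per subject-by-domain. `read_rates()` pivots
#' to a [rate_table]; `write_rates()` is its inverse.
#'
#' @param path file path of the CSV.
#' @param rates a `rate_table`.
#' @return `read_rates()` a `rate_table`; `write_rates()` the path,
#'   invisibly.
#' @export
read_rates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "arm", "domain", "rate")
  if (!all(need %in% names(d)))
    stop("rates CSV must have columns ", paste(need, collapse = ", "))
  domains <- unique(d$domain)
  wide <- stats::reshape(d[, need], direction = "wide",
                         idvar = c("subject_id", "arm"),
                         timevar = "domain", v.names = "rate")
  names(wide) <- sub("^rate\\.", "", names(wide))
  if (anyNA(wide))
    stop("every subject must have a rate for every domain")
  rate_table(wide$subject_id, wide$arm, wide[, domains, drop = FALSE])
}

#' @rdname read_rates
#' @export
write_rates <- function(rates, path) {
  stopifnot(inherits(rates, "rate_table"))
  domains <- rate_domains(rates)
  long <- do.call(rbind, lapply(domains, function(d)
    data.frame(subject_id = rates$subject_id, arm = rates$arm,
               domain = d, rate = rates[[d]], stringsAsFactors = FALSE)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
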