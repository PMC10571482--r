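## Configuration file I/O: one JSON document with optional top-level
## sections "generator" and "scenario". Unknown keys anywhere are a hard
## error so a typo cannot silently fall back to a default.

generator_keys <- c("domains", "baseline_mean", "slope_control",
                    "slope_treated", "direction", "quad_coef",
                    "std_effect", "sd_baseline_re", "sd_slope_re",
                    "sd_residual", "cross_domain_corr", "visit_months",
                    "clip_range")
scenario_keys <- c("mode", "priority_order", "threshold_fractions",
                   "n_per_arm", "n_replicates", "alpha", "n_permutations",
                   "master_seed")

check_keys <- function(given, allowed, where) {
  unknown <- setdiff(names(given), allowed)
  if (length(unknown) > 0)
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
}

#' Load generator and scenario configuration from a JSON file
#'
#' The file may supply any subset of the parameters of
#' [generator_config()] (section `"generator"`) and [scenario_config()]
#' (section `"scenario"`); everything else resolves to the documented
#' defaults. An empty file (or empty JSON object) yields the full default
#' configuration. Unknown keys and invalid values are hard errors naming
#' the offending key.
#'
#' @param path path to the JSON config file.
#' @return list with elements `generator` (a `generator_config`) and
#'   `scenario` (a `scenario_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else
    list()
  if (length(cfg) == 0) cfg <- list()
  check_keys(cfg, c("generator", "scenario"), "top-level")
  gen_args <- if (!is.null(cfg$generator)) as.list(cfg$generator) else list()
  sce_args <- if (!is.null(cfg$scenario)) as.list(cfg$scenario) else list()
  check_keys(gen_args, generator_keys, "generator")
  check_keys(sce_args, scenario_keys, "scenario")
  list(generator = do.call(generator_config, gen_args),
       scenario = do.call(scenario_config, sce_args))
}

#' Write a fully-resolved configuration back to JSON
#'
#' Serializes every resolved parameter (including derived defaults such
#' as the calibrated SDs) so that reloading the file reproduces the
#' configuration exactly and every run is self-describing.
#'
#' @param generator a `generator_config`.
#' @param scenario a `scenario_config`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(generator, scenario, path) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(scenario, "scenario_config"))
  gen <- unclass(generator)
  attr(gen, "re_covariance") <- NULL
  gen <- gen[!vapply(gen, is.null, logical(1))]
  sce <- unclass(scenario)
  sce <- sce[!vapply(sce, is.null, logical(1))]
  jsonlite::write_json(list(generator = gen, scenario = sce), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
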