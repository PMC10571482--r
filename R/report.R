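#' Write a power-study report: tidy CSVs, plots and a run manifest
#'
#' Writes `power_results.csv` (full precision), optionally
#' `deciding_outcomes.csv`, power-curve plots (skipped cleanly, with a
#' message, when no plotting backend is available), and `manifest.json`
#' recording the resolved configuration, master seed, package version,
#' timestamp and the output file inventory. Re-running from the manifest
#' with [run_from_manifest()] reproduces the CSVs byte-identically.
#'
#' @param results a `power_result` data frame (from [run_scenario()],
#'   [run_marginal_power()] or [run_ordering_sensitivity()]`$power`).
#' @param generator,scenario the configurations that produced `results`.
#' @param outdir output directory (created if needed).
#' @param deciding optional deciding-outcome table
#'   ([run_ordering_sensitivity()]`$deciding`).
#' @param plots if `TRUE` (default), attempt to render power curves.
#' @return invisibly, the manifest as a list.
#' @export
write_report <- function(results, generator, scenario, outdir,
                         deciding = NULL, plots = TRUE) {
  if (nrow(results) == 0) stop("results are empty")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character()
  csv <- file.path(outdir, "power_results.csv")
  utils::write.csv(results, csv, row.names = FALSE)
  files <- c(files, "power_results.csv")
  if (!is.null(deciding)) {
    dcsv <- file.path(outdir, "deciding_outcomes.csv")
    utils::write.csv(deciding, dcsv, row.names = FALSE)
    files <- c(files, "deciding_outcomes.csv")
  }
  cfg <- file.path(outdir, "config.json")
  write_config(generator, scenario, cfg)
  files <- c(files, "config.json")
  if (plots) {
    plotted <- plot_power_curves(results, file.path(outdir,
                                                    "power_curves.svg"))
    if (plotted) files <- c(files, "power_curves.svg")
  }
  manifest <- list(package = "gpcpower",
                   version = as.character(utils::packageVersion("gpcpower")),
                   created = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ"),
                   master_seed = scenario$master_seed,
                   config_file = "config.json",
                   files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Re-run a reported power study from its manifest
#'
#' Loads the resolved configuration stored next to a `manifest.json`,
#' re-executes [run_scenario()], and rewrites the report into `outdir`.
#' Because every random draw derives from the recorded master seed, the
#' numerical outputs are reproduced exactly.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_report()].
#' @param outdir directory for the re-run report (defaults to the
#'   manifest's own directory).
#' @param null passed through to [run_scenario()].
#' @return the re-computed `power_result`, invisibly.
#' @export
run_from_manifest <- function(manifest_path, outdir = dirname(manifest_path),
                              null = FALSE) {
  man <- jsonlite::fromJSON(manifest_path)
  cfg <- load_config(file.path(dirname(manifest_path), man$config_file))
  res <- run_scenario(cfg$scenario, cfg$generator, null = null)
  write_report(res, cfg$generator, cfg$scenario, outdir, plots = FALSE)
  invisible(res)
}

#' Plot power curves (one line per scenario/mode) to an SVG file
#'
#' Uses ggplot2 when available; otherwise emits a message and returns
#' `FALSE` so callers can degrade cleanly (CSV output is unaffected).
#'
#' @param results a `power_result` data frame.
#' @param path output SVG path.
#' @return `TRUE` if a plot was written, `FALSE` otherwise.
#' @export
plot_power_curves <- function(results, path) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    message("ggplot2 not available; skipping plot rendering")
    return(FALSE)
  }
  results$curve <- paste(results$scenario, results$mode, sep = " / ")
  p <- ggplot2::ggplot(results,
         ggplot2::aes(x = threshold_fraction, y = power, colour = curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, power - mc_se),
      ymax = pmin(1, power + mc_se)), width = 0.02) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "threshold (fraction of rate-of-change SD)",
                  y = "empirical power", colour = NULL) +
    ggplot2::theme_minimal()
  ok <- tryCatch({
    ggplot2::ggsave(path, p, device = grDevices::svg, width = 7,
                    height = 4.5)
    TRUE
  }, error = function(e) {
    message("plot rendering failed (", conditionMessage(e),
            "); continuing without plots")
    FALSE
  })
  ok
}
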