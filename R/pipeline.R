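#' Default pipeline configuration
#'
#' The knobs of the end-to-end pipeline with their package defaults, as a
#' plain list that round-trips through YAML unchanged. Flags of the
#' command-line front end override individual entries.
#'
#' @return named list: temperature program, smoothing window/order, QC
#'   thresholds, test form, multiplicity correction, seed
#' @export
defaultPipelineConfig <- function() {
  list(program = list(t_start = 25, t_end = 90, step = 1),
       window = 7L, order = 3L,
       min_amplitude = 0.2, peak_half_width = 3L, edge_margin = 2L,
       multi_peak_frac = 0.6, multi_peak_sep = 5,
       test = "one_sample", correction = "none", seed = 1L)
}

#' @rdname defaultPipelineConfig
#' @param path YAML file
#' @export
readPipelineConfig <- function(path) {
  cfg <- utils::modifyList(defaultPipelineConfig(), yaml::read_yaml(path))
  cfg$window <- as.integer(cfg$window)
  cfg$order <- as.integer(cfg$order)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname defaultPipelineConfig
#' @param config configuration list
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.callOpts <- function(cfg) {
  list(window = cfg$window, order = cfg$order,
       minAmplitude = cfg$min_amplitude,
       peakHalfWidth = cfg$peak_half_width, edgeMargin = cfg$edge_margin,
       multiPeakFrac = cfg$multi_peak_frac, multiPeakSep = cfg$multi_peak_sep)
}

#' Simulate a scenario to disk
#'
#' Writes the long-dialect melt table (\code{curves.csv}), the sample sheet
#' (\code{samples.csv}) and a provenance manifest (\code{manifest.json})
#' for a named built-in scenario or a scenario YAML file. Identical
#' invocations produce byte-identical outputs.
#'
#' @param scenario a \linkS4class{ScenarioSpec}, the name of a built-in
#'   scenario, or a path to a scenario YAML file
#' @param seed integer seed
#' @param outdir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
cmdSimulate <- function(scenario, seed = 1L, outdir = ".") {
  if (is.character(scenario)) {
    scenario <- if (file.exists(scenario) &&
                    grepl("\\.ya?ml$", scenario))
      readScenario(scenario)
    else .resolveScenario(scenario)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateScenario(scenario, seed = seed)
  paths <- c(curves = file.path(outdir, "curves.csv"),
             samples = file.path(outdir, "samples.csv"),
             manifest = file.path(outdir, "manifest.json"))
  writeMeltTable(sim$curves, paths[["curves"]])
  writeSampleSheet(sim$samples, paths[["samples"]])
  jsonlite::write_json(
    list(scenario = scenario@name, protein = scenario@protein,
         seed = seed, n_curves = length(sim$curves),
         version = as.character(utils::packageVersion("meltscreen"))),
    paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Call Tm for a melt table on disk
#'
#' @param curvesPath melt-curve CSV
#' @param out output TSV (\code{run_id, well_id, tm, peak_height,
#'   amplitude_ratio, flags})
#' @param dialect melt-table dialect, see \code{\link{readMeltTable}}
#' @param config pipeline configuration list
#' @return the calls data.frame, invisibly
#' @export
cmdCallTm <- function(curvesPath, out, dialect = "long",
                      config = defaultPipelineConfig()) {
  curves <- readMeltTable(curvesPath, dialect = dialect)
  calls <- do.call(callTmSet, c(list(curves), .callOpts(config)))
  calls$tm <- signif(calls$tm, 6)
  calls$peak_height <- signif(calls$peak_height, 6)
  calls$amplitude_ratio <- signif(calls$amplitude_ratio, 6)
  utils::write.table(calls, out, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(calls)
}

#' Run the screen stage end to end
#'
#' Reads curves and sample sheet, calls Tm per well, aggregates
#' control-subtracted shifts with significance stars, and writes the
#' report. Excluded wells and dropped runs are reported as warnings with
#' the triggering QC rule.
#'
#' @param curvesPath melt-curve CSV
#' @param samplesPath sample-sheet CSV
#' @param out report TSV path
#' @param json optional report JSON path (lossless, with per-repeat shifts)
#' @param plot optional PDF path for the shift bar chart
#' @param dialect melt-table dialect
#' @param config pipeline configuration list
#' @return the \linkS4class{ScreenReport}, invisibly
#' @export
cmdScreen <- function(curvesPath, samplesPath, out, json = NULL,
                      plot = NULL, dialect = "long",
                      config = defaultPipelineConfig()) {
  if (!file.exists(samplesPath))
    stop("sample sheet not found: ", samplesPath, call. = FALSE)
  if (!file.exists(curvesPath))
    stop("melt table not found: ", curvesPath, call. = FALSE)
  curves <- readMeltTable(curvesPath, dialect = dialect)
  samples <- readSampleSheet(samplesPath)
  calls <- do.call(callTmSet, c(list(curves), .callOpts(config)))
  flagged <- calls[nzchar(calls$flags), , drop = FALSE]
  if (nrow(flagged))
    warning(sprintf("%d well(s) QC-flagged: %s", nrow(flagged),
                    paste(sprintf("%s/%s[%s]", flagged$run_id,
                                  flagged$well_id, flagged$flags),
                          collapse = "; ")), call. = FALSE)
  report <- aggregateScreen(calls, samples, test = config$test,
                            correction = config$correction,
                            metadata = list(config = config,
                                            curves = curvesPath,
                                            samples = samplesPath))
  writeScreenReport(report, out, format = "tsv")
  if (!is.null(json)) writeScreenReport(report, json, format = "json")
  if (!is.null(plot)) {
    grDevices::pdf(plot, width = 8, height = 4.5)
    on.exit(grDevices::dev.off())
    plotScreen(report)
  }
  invisible(report)
}

#' Simulate, call and screen a scenario in memory
#'
#' Convenience wrapper chaining \code{\link{simulateScenario}},
#' \code{\link{callTmSet}} and \code{\link{aggregateScreen}}.
#'
#' @param scenario scenario object or built-in name
#' @param seed integer seed
#' @param ... passed to \code{\link{aggregateScreen}}
#' @return list with \code{report} (\linkS4class{ScreenReport}),
#'   \code{calls}, \code{samples} and \code{controlTm} (per-run control
#'   means)
#' @examples
#' res <- screenScenario("aac", seed = 42)
#' records(res$report)[, c("compound", "mean_delta_tm_C", "stars")]
#' @export
screenScenario <- function(scenario, seed = 1L, ...) {
  if (is.character(scenario)) scenario <- .resolveScenario(scenario)
  sim <- simulateScenario(scenario, seed = seed)
  calls <- callTmSet(sim$curves)
  report <- aggregateScreen(calls, sim$samples,
                            metadata = list(scenario = scenario@name,
                                            seed = seed), ...)
  list(report = report, calls = calls, samples = sim$samples,
       controlTm = runControlTm(calls, sim$samples))
}

#' Bar chart of a screen report
#'
#' Mean temperature shift per compound with +/- sd error bars and the star
#' class above each bar, one panel per condition; the figure mirrors the
#' conventional thermostability-screen bar chart. Advisory only; all
#' downstream analysis reads the tabular report.
#'
#' @param report a \linkS4class{ScreenReport}
#' @param conditions conditions to draw (default: all in the report)
#' @return invisible NULL
#' @export
plotScreen <- function(report, conditions = NULL) {
  r <- records(report)
  if (is.null(conditions)) conditions <- unique(r$condition)
  old <- graphics::par(mfrow = c(length(conditions), 1),
                       mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cond in conditions) {
    rc <- r[r$condition == cond, , drop = FALSE]
    rc <- rc[order(-rc$mean_delta_tm_C), , drop = FALSE]
    ylim <- range(0, rc$mean_delta_tm_C + rc$sd_delta_tm_C,
                  rc$mean_delta_tm_C - rc$sd_delta_tm_C, na.rm = TRUE)
    mid <- graphics::barplot(rc$mean_delta_tm_C, names.arg = rc$compound,
                             las = 2, cex.names = 0.6,
                             ylim = ylim * 1.15,
                             ylab = expression(Delta * T[m] ~ (degree * C)),
                             main = cond)
    ok <- !is.na(rc$sd_delta_tm_C) & rc$sd_delta_tm_C > 0
    graphics::arrows(mid[ok], rc$mean_delta_tm_C[ok] - rc$sd_delta_tm_C[ok],
                     mid[ok], rc$mean_delta_tm_C[ok] + rc$sd_delta_tm_C[ok],
                     angle = 90, code = 3, length = 0.02)
    lab <- ifelse(rc$stars == "ns", "", rc$stars)
    graphics::text(mid, rc$mean_delta_tm_C +
                     ifelse(is.na(rc$sd_delta_tm_C), 0, rc$sd_delta_tm_C) +
                     0.03 * diff(ylim), lab, cex = 0.7)
  }
  invisible(NULL)
}
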