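#' Read a melt-curve table
#'
#' Parses a plate export into a \linkS4class{MeltCurveSet}. Two neutral CSV
#' dialects are supported; instrument exports are expected to be converted
#' to one of them beforehand.
#' \describe{
#'   \item{long}{columns \code{run_id, well, temperature_C, fluorescence};
#'     one row per reading, any row order.}
#'   \item{wide}{first column \code{temperature_C}, then one column per
#'     well; a single run whose id is taken from \code{runId}.}
#' }
#' Rows are sorted by temperature per well; duplicate (well, temperature)
#' readings are an error, as are wells with fewer than 10 points.
#'
#' @param path CSV file path
#' @param dialect \code{"long"} or \code{"wide"}
#' @param runId run identifier assigned to wide-dialect curves
#' @return a \linkS4class{MeltCurveSet}
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(temperature_C = 25:90, A1 = seq(10, 110, length = 66)),
#'           tf, row.names = FALSE)
#' curves <- readMeltTable(tf, dialect = "wide")
#' length(curves)
#' @export
readMeltTable <- function(path, dialect = c("long", "wide"),
                          runId = "run1") {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (dialect == "long") {
    need <- c("run_id", "well", "temperature_C", "fluorescence")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("melt table format error: missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    keys <- split(df, list(df$run_id, df$well), drop = TRUE, sep = "\r")
    curves <- lapply(keys, function(d) {
      d <- d[order(d$temperature_C), , drop = FALSE]
      if (anyDuplicated(d$temperature_C))
        stop(sprintf(
          "melt table data error: duplicate temperature readings for well %s (run %s)",
          d$well[1], d$run_id[1]), call. = FALSE)
      .asMeltCurve(d$well[1], d$run_id[1], d$temperature_C, d$fluorescence)
    })
    ord <- order(vapply(curves, function(x) x@runId, character(1)),
                 vapply(curves, function(x) x@wellId, character(1)))
    MeltCurveSet(unname(curves[ord]))
  } else {
    if (!identical(names(df)[1], "temperature_C"))
      stop("melt table format error: missing column temperature_C",
           call. = FALSE)
    if (ncol(df) < 2L)
      stop("melt table format error: wide table has no well columns",
           call. = FALSE)
    df <- df[order(df$temperature_C), , drop = FALSE]
    if (anyDuplicated(df$temperature_C))
      stop("melt table data error: duplicate temperature rows",
           call. = FALSE)
    curves <- lapply(names(df)[-1], function(w)
      .asMeltCurve(w, runId, df$temperature_C, df[[w]]))
    MeltCurveSet(curves)
  }
}

.asMeltCurve <- function(well, run, temps, fluo) {
  if (length(temps) < 10L)
    stop(sprintf("melt table data error: well %s has fewer than 10 points",
                 well), call. = FALSE)
  if (anyNA(fluo) || any(!is.finite(fluo)))
    stop(sprintf("melt table data error: non-finite fluorescence in well %s",
                 well), call. = FALSE)
  MeltCurve(well, temps, fluo, runId = run)
}

#' Write a melt-curve table
#'
#' Inverse of \code{\link{readMeltTable}}; always writes the long dialect.
#'
#' @param curves a \linkS4class{MeltCurveSet}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeMeltTable <- function(curves, path) {
  rows <- lapply(as.list(curves), function(cv)
    data.frame(run_id = runId(cv), well = wellId(cv),
               temperature_C = temperatures(cv),
               fluorescence = fluorescence(cv)))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet maps wells to their experimental annotation. Required
#' columns: \code{run_id, well_id, protein, compound, concentration_mM,
#' ph, ions, role, bio_rep}. \code{role} is \code{"control"} (no-ligand
#' well, empty \code{compound}) or \code{"test"}; \code{ions} uses the
#' \code{"Na=140;K=5"} encoding, possibly empty. Every run must contain at
#' least one control well, since temperature shifts are defined against
#' in-run controls.
#'
#' @param path CSV file path
#' @return a validated data.frame of well annotations
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ions = "character",
                                       compound = "character"))
  validateSampleSheet(df)
}

#' @rdname readSampleSheet
#' @param annotations a data.frame with the sample-sheet columns
#' @export
validateSampleSheet <- function(annotations) {
  need <- c("run_id", "well_id", "protein", "compound", "concentration_mM",
            "ph", "ions", "role", "bio_rep")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("sample sheet format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  annotations$compound[is.na(annotations$compound)] <- ""
  annotations$ions[is.na(annotations$ions)] <- ""
  if (!all(annotations$role %in% c("control", "test")))
    stop("sample sheet validation error: role must be 'control' or 'test'",
         call. = FALSE)
  bad <- annotations$role == "control" & nzchar(annotations$compound)
  if (any(bad))
    stop("sample sheet validation error: control wells must have no compound (",
         paste(annotations$well_id[bad], collapse = ", "), ")",
         call. = FALSE)
  if (any(annotations$concentration_mM < 0, na.rm = TRUE))
    stop("sample sheet validation error: negative concentration",
         call. = FALSE)
  key <- paste(annotations$run_id, annotations$well_id, sep = "\r")
  if (anyDuplicated(key))
    stop("sample sheet validation error: duplicate (run_id, well_id) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  ctrl <- tapply(annotations$role == "control", annotations$run_id, any)
  if (!all(ctrl))
    stop("sample sheet validation error: run(s) without control wells: ",
         paste(names(ctrl)[!ctrl], collapse = ", "),
         " (delta-Tm undefined without controls)", call. = FALSE)
  invisible(lapply(annotations$ions, parseIons))  # syntax check
  annotations
}

#' Write a sample sheet
#'
#' @param annotations sample-sheet data.frame (see
#'   \code{\link{readSampleSheet}})
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeSampleSheet <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

.REPORT_COLS <- c("protein", "compound", "condition", "n",
                  "mean_delta_tm_C", "sd_delta_tm_C", "p_value", "stars")

#' Write a screen report
#'
#' TSV output carries the flat columns \code{protein, compound, condition,
#' n, mean_delta_tm_C, sd_delta_tm_C, p_value, stars} (numbers at 6
#' significant digits); JSON output additionally keeps the per-repeat
#' shifts and excluded wells, losslessly, plus the metadata.
#'
#' @param report a \linkS4class{ScreenReport}
#' @param path output path
#' @param format \code{"tsv"} or \code{"json"}
#' @return \code{path}, invisibly
#' @export
writeScreenReport <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  r <- records(report)
  if (format == "tsv") {
    out <- r[, .REPORT_COLS, drop = FALSE]
    for (col in c("mean_delta_tm_C", "sd_delta_tm_C", "p_value"))
      out[[col]] <- signif(out[[col]], 6)
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    flat <- r[, .REPORT_COLS, drop = FALSE]
    flat$per_rep_delta <- unname(r$per_rep_delta)
    flat$excluded_wells <- unname(r$excluded_wells)
    obj <- list(records = flat, metadata = reportMetadata(report))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' Read a screen report
#'
#' @param path file written by \code{\link{writeScreenReport}}
#' @param format \code{"tsv"} or \code{"json"}
#' @return a \linkS4class{ScreenReport}; TSV input yields empty per-repeat
#'   list-columns (the flat format does not carry them)
#' @export
readScreenReport <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    r <- utils::read.delim(path, stringsAsFactors = FALSE)
    r$per_rep_delta <- rep(list(numeric(0)), nrow(r))
    r$excluded_wells <- rep(list(data.frame()), nrow(r))
    ScreenReport(r, metadata = list(source = path))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    r <- obj$records
    if (is.null(r$per_rep_delta)) {
      r$per_rep_delta <- rep(list(numeric(0)), nrow(r))
    } else if (!is.list(r$per_rep_delta)) {
      r$per_rep_delta <- as.list(as.data.frame(t(r$per_rep_delta)))
    }
    r$per_rep_delta <- lapply(r$per_rep_delta, as.numeric)
    if (is.null(r$excluded_wells))
      r$excluded_wells <- rep(list(data.frame()), nrow(r))
    r$p_value <- as.numeric(r$p_value)
    ScreenReport(as.data.frame(r),
                 metadata = if (is.null(obj$metadata)) list()
                            else obj$metadata)
  }
}
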