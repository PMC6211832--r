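#' Per-run control Tm
#'
#' The reference temperature of each instrument run is the arithmetic mean
#' of the apparent Tm of its unflagged no-ligand control wells (technical
#' repeats within the run). Runs whose controls are all QC-flagged cannot
#' anchor a temperature shift: they are dropped with a warning, and an
#' error is raised if no run survives.
#'
#' @param calls data.frame from \code{\link{callTmSet}}
#' @param samples sample-sheet data.frame (see
#'   \code{\link{readSampleSheet}})
#' @return data.frame with columns \code{run_id, control_tm, n_controls}
#' @export
runControlTm <- function(calls, samples) {
  ann <- samples[samples$role == "control",
                 c("run_id", "well_id"), drop = FALSE]
  m <- merge(ann, calls, by = c("run_id", "well_id"))
  usable <- m[!nzchar(m$flags), , drop = FALSE]
  runs <- unique(samples$run_id)
  out <- do.call(rbind, lapply(runs, function(r) {
    tms <- usable$tm[usable$run_id == r]
    if (!length(tms)) return(NULL)
    data.frame(run_id = r, control_tm = mean(tms),
               n_controls = length(tms), stringsAsFactors = FALSE)
  }))
  dropped <- setdiff(runs, out$run_id)
  if (length(dropped))
    warning("run(s) excluded, no usable control wells: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (is.null(out) || !nrow(out))
    stop("no run has a usable control well; delta-Tm undefined",
         call. = FALSE)
  out
}

#' Control-subtracted temperature shifts
#'
#' Delta-Tm of each test well is its apparent Tm minus the mean control Tm
#' of the same run; the sign is kept, so destabilizing compounds come out
#' negative. QC-flagged test wells contribute no shift; they are recorded
#' in the \code{excluded} attribute (and propagated into
#' \code{excluded_wells} of the screen report).
#'
#' @inheritParams runControlTm
#' @return data.frame with one row per usable (compound, run): columns
#'   \code{protein, compound, condition, run_id, bio_rep, delta_tm,
#'   control_tm}; attribute \code{excluded} lists flagged test wells
#' @export
computeDeltaTm <- function(calls, samples) {
  ctrl <- runControlTm(calls, samples)
  tests <- samples[samples$role == "test", , drop = FALSE]
  m <- merge(tests, calls, by = c("run_id", "well_id"))
  m <- merge(m, ctrl, by = "run_id")   # runs without controls drop out
  m$condition <- mapply(conditionLabel, m$ph, m$ions)
  flagged <- nzchar(m$flags)
  excluded <- m[flagged, c("run_id", "well_id", "compound", "flags"),
                drop = FALSE]
  ok <- m[!flagged, , drop = FALSE]
  out <- data.frame(protein = ok$protein, compound = ok$compound,
                    condition = ok$condition, run_id = ok$run_id,
                    bio_rep = ok$bio_rep,
                    delta_tm = ok$tm - ok$control_tm,
                    control_tm = ok$control_tm, stringsAsFactors = FALSE)
  out <- out[order(out$protein, out$condition, out$compound, out$bio_rep), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Welch's unequal-variance t-test
#'
#' Two-tailed two-sample t-test without the equal-variance assumption
#' (Satterthwaite degrees of freedom), as used to judge whether a
#' compound's Tm replicates differ from the control Tm replicates.
#' Degenerate inputs are resolved explicitly: two samples with zero
#' variance and equal means give p = 1; zero variance with unequal means is
#' the p -> 0 limit, reported as the smallest positive double.
#'
#' @param x,y numeric samples, each of length >= 2
#' @return list with elements \code{t}, \code{df}, \code{p}
#' @examples
#' welchTTest(c(63.2, 63.4, 63.3), c(57.5, 57.7, 57.6))
#' @export
welchTTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("welchTTest requires at least 2 observations per sample",
         call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  se <- sqrt(vx / length(x) + vy / length(y))
  if (se <= 10 * .Machine$double.eps * max(1, abs(mean(x)), abs(mean(y)))) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_,
                p = .Machine$double.xmin))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

# One-sample t on the per-run shifts against the null delta-Tm = 0. This is
# the run-paired form: in-run control subtraction removes the shared batch
# jitter, so the replicate shifts are independent. Zero-variance samples
# are resolved as in welchTTest.
.oneSampleP <- function(d) {
  if (length(d) < 2L) return(NA_real_)
  # exactly (or numerically) constant shifts: the p -> 1 or p -> 0 limit
  if (stats::sd(d) <= 10 * .Machine$double.eps * max(1, abs(mean(d)))) {
    if (mean(d) == 0) return(1)
    return(.Machine$double.xmin)
  }
  stats::t.test(d, mu = 0)$p.value
}

#' Star classification of a p-value
#'
#' The conventional screening star scheme: p < 0.0001 "****",
#' < 0.001 "***", < 0.01 "**", < 0.05 "*", otherwise "ns". Boundary values
#' fall in the less significant class (p = 0.05 is "ns", p = 0.01 is "*").
#'
#' @param p p-value(s) in (0, 1]
#' @return character vector of star labels
#' @examples
#' classifySignificance(c(0.03, 0.2, 5e-6))
#' @export
classifySignificance <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  ifelse(p < 1e-4, "****",
    ifelse(p < 1e-3, "***",
      ifelse(p < 1e-2, "**",
        ifelse(p < 5e-2, "*", "ns"))))
}

#' Aggregate Tm calls into a screen report
#'
#' Builds one \code{ShiftRecord} row per (protein, compound, condition):
#' the per-biological-repeat control-subtracted shifts, their mean and sd,
#' and a two-tailed p-value against the null of zero shift. Two test forms
#' are available: \code{"one_sample"} (default), the run-paired one-sample
#' t on the per-run shifts, and \code{"welch"}, the two-sample
#' unequal-variance t of test-well Tm against the per-run control means.
#' The forms coincide when there is no between-run variation; with real
#' batch-to-batch scatter the paired form keeps its nominal error rate
#' while the two-sample form is conservative (the run effect inflates both
#' samples but cancels in the paired differences).
#'
#' Compounds with fewer than two usable repeats get \code{p_value = NA} and
#' stars \code{"ns"}. QC-excluded wells reduce n; nothing is imputed. With
#' \code{correction = "bh"} stars are assigned from Benjamini-Hochberg
#' adjusted p-values (no correction by default, matching common screening
#' practice).
#'
#' @inheritParams runControlTm
#' @param test \code{"one_sample"} or \code{"welch"}
#' @param correction \code{"none"} or \code{"bh"}
#' @param metadata list stored in the report (seed provenance etc.)
#' @return a \linkS4class{ScreenReport}
#' @export
aggregateScreen <- function(calls, samples,
                            test = c("one_sample", "welch"),
                            correction = c("none", "bh"),
                            metadata = list()) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  deltas <- computeDeltaTm(calls, samples)
  excluded <- attr(deltas, "excluded")
  ctrl <- runControlTm(calls, samples)

  # control Tm replicates for the two-sample form: per-run control means
  testTm <- merge(samples[samples$role == "test", , drop = FALSE], calls,
                  by = c("run_id", "well_id"))
  testTm <- testTm[!nzchar(testTm$flags), , drop = FALSE]
  testTm$condition <- mapply(conditionLabel, testTm$ph, testTm$ions)

  key <- unique(deltas[, c("protein", "compound", "condition")])
  recs <- lapply(seq_len(nrow(key)), function(k) {
    sel <- deltas$protein == key$protein[k] &
      deltas$compound == key$compound[k] &
      deltas$condition == key$condition[k]
    d <- deltas$delta_tm[sel]
    runs <- deltas$run_id[sel]
    p <- if (length(d) < 2L) NA_real_
         else if (test == "one_sample") .oneSampleP(d)
         else welchTTest(
           testTm$tm[testTm$compound == key$compound[k] &
                       testTm$condition == key$condition[k] &
                       testTm$run_id %in% runs],
           ctrl$control_tm[ctrl$run_id %in% runs])$p
    exc <- excluded[excluded$compound == key$compound[k], , drop = FALSE]
    data.frame(protein = key$protein[k], compound = key$compound[k],
               condition = key$condition[k], n = length(d),
               mean_delta_tm_C = mean(d),
               sd_delta_tm_C = if (length(d) > 1L) stats::sd(d)
                               else NA_real_,
               p_value = p,
               per_rep_delta = I(list(d)),
               excluded_wells = I(list(exc)),
               stringsAsFactors = FALSE)
  })
  r <- do.call(rbind, recs)
  padj <- r$p_value
  if (correction == "bh")
    padj[!is.na(padj)] <- stats::p.adjust(padj[!is.na(padj)],
                                          method = "BH")
  r$stars <- "ns"
  ok <- !is.na(padj)
  r$stars[ok] <- classifySignificance(padj[ok])
  r <- r[, c("protein", "compound", "condition", "n", "mean_delta_tm_C",
             "sd_delta_tm_C", "p_value", "stars", "per_rep_delta",
             "excluded_wells")]
  rownames(r) <- NULL
  meta <- c(metadata,
            list(test = test, correction = correction,
                 n_excluded_wells = nrow(excluded),
                 package_version = as.character(
                   utils::packageVersion("meltscreen"))))
  ScreenReport(r, metadata = meta)
}

#' Rank significant hits
#'
#' Records at or above the star threshold, in descending order of mean
#' shift; ties resolve toward the smaller p-value.
#'
#' @param report a \linkS4class{ScreenReport}
#' @param minStars minimum star class (\code{"*"} by default)
#' @return the selected records, ordered
#' @export
rankHits <- function(report, minStars = "*") {
  stopifnot(minStars %in% .STAR_LEVELS)
  r <- records(report)
  r <- r[starRank(r$stars) >= starRank(minStars), , drop = FALSE]
  r <- r[order(-r$mean_delta_tm_C, r$p_value), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Contrast a compound panel between two conditions
#'
#' Delta-delta-Tm per compound between two condition labels of a report (or
#' between two reports): mean shift under \code{a} minus mean shift under
#' \code{b}, with the root-sum-square of the two standard errors and a
#' Welch test on the two per-repeat shift samples. A positive value means
#' stronger stabilization under \code{a}, e.g. proton-assisted substrate
#' binding probed at acidic vs basic pH, or coupling-ion-dependent binding
#' probed across ion compositions. Compounds present under only one
#' condition are omitted with a warning.
#'
#' @param report a \linkS4class{ScreenReport} (or the report for
#'   condition a, when \code{reportB} is given)
#' @param a,b condition labels present in \code{report}
#' @param reportB optional second report; then \code{a}/\code{b} default to
#'   the single condition of each report
#' @return data.frame with columns \code{protein, compound, condition_a,
#'   condition_b, delta_delta_tm_C, se_delta_delta_tm_C, p_value, stars}
#' @export
conditionContrast <- function(report, a = NULL, b = NULL, reportB = NULL) {
  ra <- records(report)
  rb <- if (is.null(reportB)) ra else records(reportB)
  if (is.null(a)) a <- unique(ra$condition)[1]
  if (is.null(b))
    b <- if (is.null(reportB)) unique(ra$condition)[2]
         else unique(rb$condition)[1]
  ra <- ra[ra$condition == a, , drop = FALSE]
  rb <- rb[rb$condition == b, , drop = FALSE]
  if (!nrow(ra) || !nrow(rb))
    stop("condition label(s) not found in report", call. = FALSE)
  common <- intersect(ra$compound, rb$compound)
  only <- union(setdiff(ra$compound, common), setdiff(rb$compound, common))
  if (length(only))
    warning("compound(s) present under only one condition, omitted: ",
            paste(only, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(common, function(cp) {
    xa <- ra$per_rep_delta[[which(ra$compound == cp)]]
    xb <- rb$per_rep_delta[[which(rb$compound == cp)]]
    wt <- if (length(xa) >= 2L && length(xb) >= 2L) welchTTest(xa, xb)
          else list(p = NA_real_)
    sea <- stats::sd(xa) / sqrt(length(xa))
    seb <- stats::sd(xb) / sqrt(length(xb))
    data.frame(protein = ra$protein[ra$compound == cp][1], compound = cp,
               condition_a = a, condition_b = b,
               delta_delta_tm_C = mean(xa) - mean(xb),
               se_delta_delta_tm_C = sqrt(sea^2 + seb^2),
               p_value = wt$p, stringsAsFactors = FALSE)
  }))
  out$stars <- "ns"
  ok <- !is.na(out$p_value)
  out$stars[ok] <- classifySignificance(out$p_value[ok])
  out[order(-out$delta_delta_tm_C), , drop = FALSE]
}
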