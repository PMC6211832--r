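#' Savitzky-Golay smoothing of a melt curve
#'
#' Least-squares local-polynomial smoothing on the uniform temperature
#' grid (via \code{signal::sgolayfilt}). A polynomial of degree <= order
#' passes through unchanged, so the filter does not distort the gross shape
#' of a two-state transition while suppressing reading noise.
#'
#' @param curve a \linkS4class{MeltCurve} on a uniform grid
#' @param window odd filter length, 3 <= window <= n (default 7)
#' @param order polynomial order < window (default 3)
#' @return a smoothed \linkS4class{MeltCurve} on the same grid
#' @export
smoothCurve <- function(curve, window = 7L, order = 3L) {
  .checkUniform(curve)
  n <- length(curve@temperatures)
  if (window %% 2L != 1L || window < 3L || window > n)
    stop("window must be odd and within [3, n]", call. = FALSE)
  if (order >= window)
    stop("order must be < window", call. = FALSE)
  sm <- signal::sgolayfilt(curve@fluorescence, p = order, n = window)
  MeltCurve(curve@wellId, curve@temperatures, sm, runId = curve@runId)
}

.checkUniform <- function(curve, tol = 1e-6) {
  d <- diff(curve@temperatures)
  if (diff(range(d)) > tol)
    stop("non-uniform temperature grid; resample the curve onto a uniform",
         " grid before smoothing/derivative analysis", call. = FALSE)
  invisible(d[1])
}

#' First derivative of a melt curve
#'
#' dF/dT by central differences at interior points and one-sided
#' differences at the ends; same length as the input.
#'
#' @param curve a \linkS4class{MeltCurve} on a uniform grid
#' @return two-column matrix with columns \code{temperature_C},
#'   \code{dFdT}
#' @export
derivativeCurve <- function(curve) {
  h <- .checkUniform(curve)
  F <- curve@fluorescence
  n <- length(F)
  d <- c(F[2] - F[1],
         (F[3:n] - F[1:(n - 2)]) / 2,
         F[n] - F[n - 1]) / h
  cbind(temperature_C = curve@temperatures, dFdT = d)
}

# Least-squares parabola vertex around index i of (x, y); falls back to the
# grid point when the fit is not concave. Ties at the maximum resolve to
# the lower temperature through which.max.
.parabolicVertex <- function(x, y, i, half) {
  lo <- max(1L, i - half); hi <- min(length(x), i + half)
  xx <- x[lo:hi] - x[i]; yy <- y[lo:hi]
  X <- cbind(1, xx, xx^2)
  co <- stats::.lm.fit(X, yy)$coefficients
  if (!is.finite(co[3]) || co[3] >= 0) return(x[i])
  v <- x[i] - co[2] / (2 * co[3])
  # keep the vertex inside the fit window; a runaway vertex means the
  # local quadratic model is inadequate and the grid point is safer
  min(max(v, x[lo]), x[hi])
}

#' Call the apparent melting temperature of one curve
#'
#' The apparent Tm is the temperature at which the rate of unfolding of the
#' population is highest, read out as the peak of the derivative of the
#' melt curve. Pipeline: Savitzky-Golay smoothing, central-difference
#' derivative, global maximum of +dF/dT (post-transition signal decline
#' gives negative slopes, which are ignored), then sub-grid refinement of
#' the peak by a least-squares parabola over \code{peakHalfWidth} grid
#' points on each side. Linear baselines of modest slope are deliberately
#' not subtracted: they displace the derivative peak negligibly.
#'
#' Quality control is expressed through flags, never exceptions:
#' \code{no_transition} when the transition rise (integral of the
#' baseline-corrected positive derivative around the peak) is below
#' \code{minAmplitude} of the total signal range; \code{edge_peak} when the
#' maximum lies within \code{edgeMargin} grid points of either ramp end;
#' \code{multi_peak} when a secondary derivative peak at least
#' \code{multiPeakSep} degrees C away reaches \code{multiPeakFrac} of the
#' main peak height. Flagged calls keep their Tm but are excluded from
#' screen statistics by default.
#'
#' @param curve a \linkS4class{MeltCurve}
#' @param window,order smoothing parameters, see \code{\link{smoothCurve}}
#' @param minAmplitude QC threshold on the transition rise / signal range
#'   ratio (default 0.2)
#' @param peakHalfWidth half-width (grid points) of the parabolic vertex
#'   fit (default 3)
#' @param edgeMargin grid points from the ramp ends flagged as edge peaks
#' @param multiPeakFrac,multiPeakSep secondary-peak height fraction and
#'   minimum separation (degrees C)
#' @return a \linkS4class{TmCall}
#' @examples
#' cv <- simulateCurve(UnfoldingParams(noiseSd = 0), seed = 1)
#' callTm(cv)
#' @export
callTm <- function(curve, window = 7L, order = 3L, minAmplitude = 0.2,
                   peakHalfWidth = 3L, edgeMargin = 2L,
                   multiPeakFrac = 0.6, multiPeakSep = 5) {
  sm <- smoothCurve(curve, window = window, order = order)
  der <- derivativeCurve(sm)
  Tg <- der[, "temperature_C"]
  d <- der[, "dFdT"]
  n <- length(d)
  h <- Tg[2] - Tg[1]
  i <- which.max(d)
  flags <- character()

  # transition rise: baseline-corrected positive derivative integrated over
  # the contiguous region around the peak where dF/dT exceeds its median
  # (the median tracks the baseline slope). A straight line has d ~ median
  # everywhere, hence rise ~ 0.
  b <- stats::median(d)
  above <- d > b
  lo <- i; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- i; while (hi < n && above[hi + 1L]) hi <- hi + 1L
  rise <- sum(pmax(d[lo:hi] - b, 0)) * h
  rng <- diff(range(sm@fluorescence))
  ampRatio <- if (rng > 0) rise / rng else 0
  if (ampRatio < minAmplitude) flags <- c(flags, "no_transition")

  if (i <= edgeMargin || i > n - edgeMargin) flags <- c(flags, "edge_peak")

  # secondary peaks: local maxima outside the separation window
  locmax <- which(d > c(-Inf, d[-n]) & d >= c(d[-1], -Inf))
  locmax <- setdiff(locmax, i)
  far <- locmax[abs(Tg[locmax] - Tg[i]) >= multiPeakSep]
  if (length(far) && any((d[far] - b) >= multiPeakFrac * (d[i] - b)))
    flags <- c(flags, "multi_peak")

  tm <- if ("edge_peak" %in% flags) Tg[i]
        else .parabolicVertex(Tg, d, i, peakHalfWidth)

  new("TmCall", wellId = curve@wellId, runId = curve@runId, tm = tm,
      peakHeight = d[i], amplitudeRatio = ampRatio,
      flags = unique(flags), derivative = der)
}

#' Call Tm for every curve in a set
#'
#' @param curves a \linkS4class{MeltCurveSet}
#' @param ... passed to \code{\link{callTm}}
#' @return a data.frame with one row per curve: \code{run_id, well_id,
#'   tm, peak_height, amplitude_ratio, flags} (comma-joined, empty when
#'   clean)
#' @export
callTmSet <- function(curves, ...) {
  calls <- lapply(as.list(curves), callTm, ...)
  data.frame(
    run_id = vapply(calls, function(x) x@runId, character(1)),
    well_id = vapply(calls, function(x) x@wellId, character(1)),
    tm = vapply(calls, function(x) x@tm, numeric(1)),
    peak_height = vapply(calls, function(x) x@peakHeight, numeric(1)),
    amplitude_ratio = vapply(calls, function(x) x@amplitudeRatio,
                             numeric(1)),
    flags = vapply(calls, function(x) paste(x@flags, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
}
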