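#' Temperature ramp of a melt experiment
#'
#' Describes the temperature program of a thermal denaturation run as a
#' uniform grid from \code{tStart} to \code{tEnd} in steps of \code{step}
#' (all degrees Celsius). The default, 25 to 90 degrees C in 1 degree steps
#' (66 readings), matches the usual ramp of dye-based stability assays on
#' rotary qPCR instruments.
#'
#' @slot tStart numeric(1), first temperature (degrees C)
#' @slot tEnd numeric(1), last temperature (degrees C)
#' @slot step numeric(1), grid spacing (degrees C), positive
#'
#' @param tStart,tEnd,step see slots
#' @return \code{TemperatureProgram()} returns a validated object;
#'   \code{programGrid()} the temperature grid as a numeric vector.
#' @examples
#' prog <- TemperatureProgram()
#' head(programGrid(prog))
#' @aliases TemperatureProgram
#' @export TemperatureProgram
#' @exportClass TemperatureProgram
setClass("TemperatureProgram",
  representation(tStart = "numeric", tEnd = "numeric", step = "numeric"),
  prototype(tStart = 25, tEnd = 90, step = 1))

setValidity("TemperatureProgram", function(object) {
  msg <- character()
  if (length(object@tStart) != 1L || length(object@tEnd) != 1L ||
      length(object@step) != 1L)
    msg <- c(msg, "tStart, tEnd and step must be scalars")
  else {
    if (!(object@tStart < object@tEnd))
      msg <- c(msg, "tStart must be < tEnd")
    if (!(object@step > 0))
      msg <- c(msg, "step must be > 0")
  }
  if (length(msg)) msg else TRUE
})

TemperatureProgram <- function(tStart = 25, tEnd = 90, step = 1) {
  new("TemperatureProgram", tStart = tStart, tEnd = tEnd, step = step)
}

#' @rdname TemperatureProgram-class
#' @param program a \code{TemperatureProgram}
#' @export
programGrid <- function(program) {
  seq(program@tStart, program@tEnd, by = program@step)
}

#' Single-well melt curve
#'
#' Fluorescence F(T) of one well over the temperature ramp. Temperatures are
#' strictly increasing degrees Celsius; fluorescence is in arbitrary units.
#' A valid curve has at least 10 readings and no missing values: the assay
#' grid is dense, so gaps signal a corrupt export and are rejected rather
#' than interpolated.
#'
#' @slot wellId character(1) well label (e.g. "A1")
#' @slot runId character(1) identifier of the instrument run the well
#'   belongs to; control averaging and delta-Tm subtraction are within-run
#' @slot temperatures numeric, degrees C, strictly increasing
#' @slot fluorescence numeric, arbitrary units, same length
#'
#' @param wellId,runId,temperatures,fluorescence see slots
#' @aliases MeltCurve
#' @export MeltCurve
#' @exportClass MeltCurve
setClass("MeltCurve",
  representation(wellId = "character", runId = "character",
                 temperatures = "numeric", fluorescence = "numeric"))

setValidity("MeltCurve", function(object) {
  msg <- character()
  if (length(object@wellId) != 1L || length(object@runId) != 1L)
    msg <- c(msg, "wellId and runId must be single strings")
  n <- length(object@temperatures)
  if (n != length(object@fluorescence))
    msg <- c(msg, "temperatures and fluorescence must have equal length")
  if (n < 10L)
    msg <- c(msg, sprintf("fewer than 10 points (%d)", n))
  if (n >= 2L && any(diff(object@temperatures) <= 0))
    msg <- c(msg, "temperatures must be strictly increasing")
  if (anyNA(object@fluorescence) || any(!is.finite(object@fluorescence)))
    msg <- c(msg, "all fluorescence values must be finite")
  if (length(msg)) msg else TRUE
})

MeltCurve <- function(wellId, temperatures, fluorescence, runId = "run1") {
  new("MeltCurve", wellId = as.character(wellId), runId = as.character(runId),
      temperatures = as.numeric(temperatures),
      fluorescence = as.numeric(fluorescence))
}

#' @rdname MeltCurve-class
#' @export
setMethod("wellId", "MeltCurve", function(x) x@wellId)
#' @rdname MeltCurve-class
#' @export
setMethod("runId", "MeltCurve", function(x) x@runId)
#' @rdname MeltCurve-class
#' @export
setMethod("temperatures", "MeltCurve", function(x) x@temperatures)
#' @rdname MeltCurve-class
#' @export
setMethod("fluorescence", "MeltCurve", function(x) x@fluorescence)

setMethod("show", "MeltCurve", function(object) {
  cat(sprintf("MeltCurve %s/%s: %d points, %.1f-%.1f degC, F range %.3g-%.3g\n",
              object@runId, object@wellId, length(object@temperatures),
              min(object@temperatures), max(object@temperatures),
              min(object@fluorescence), max(object@fluorescence)))
})

#' Collection of melt curves
#'
#' A \code{SimpleList} of \linkS4class{MeltCurve} objects, usually one plate
#' or one simulated scenario. Standard list operations (\code{length},
#' \code{[[}, \code{lapply}) apply.
#'
#' @param curves a list of \code{MeltCurve} objects
#' @aliases MeltCurveSet
#' @export MeltCurveSet
#' @exportClass MeltCurveSet
#' @importClassesFrom S4Vectors SimpleList
setClass("MeltCurveSet", contains = "SimpleList",
         prototype = prototype(elementType = "MeltCurve"))

MeltCurveSet <- function(curves = list()) {
  ans <- S4Vectors::SimpleList(curves)
  ans <- new("MeltCurveSet", ans)
  ans@elementType <- "MeltCurve"
  validObject(ans)
  ans
}

setValidity("MeltCurveSet", function(object) {
  ok <- vapply(as.list(object), is, logical(1), class2 = "MeltCurve")
  if (all(ok)) TRUE else "all elements must be MeltCurve objects"
})

setMethod("show", "MeltCurveSet", function(object) {
  cat(sprintf("MeltCurveSet of %d curves (%d runs)\n", length(object),
              length(unique(vapply(as.list(object), runId, character(1))))))
})

#' Two-state unfolding parameters of one protein preparation
#'
#' Parameters of the two-state van't Hoff unfolding model with linear
#' native/unfolded baselines that generates a CPM-style melt curve:
#' \deqn{F(T) = (a_n + b_n T)(1 - f_u(T)) + (a_u + b_u T) f_u(T) + \epsilon}
#' with \eqn{f_u} the fraction unfolded (see \code{\link{fractionUnfolded}})
#' and \eqn{\epsilon \sim N(0, \sigma)}. Because the thiol probe reacts with
#' cysteines exposed on unfolding, the unfolded baseline is the brighter one
#' (\code{aU > aN}).
#'
#' @slot tm0 numeric(1), apo midpoint (degrees C)
#' @slot dhVH numeric(1), van't Hoff enthalpy at the midpoint (J/mol), > 0.
#'   Default 5e5 J/mol (500 kJ/mol), a sharp transition with 10-90\% width
#'   of about 8 degrees C, typical of detergent-solubilised transporters in
#'   this assay.
#' @slot aN,bN numeric(1), native baseline intercept (AU) and slope (AU/degC)
#' @slot aU,bU numeric(1), unfolded baseline intercept and slope
#' @slot noiseSd numeric(1), additive per-reading noise sd (AU), >= 0.
#'   Default 1.7 AU, i.e. 2\% of the default transition amplitude.
#'
#' @param tm0,dhVH,aN,bN,aU,bU,noiseSd see slots
#' @aliases UnfoldingParams
#' @export UnfoldingParams
#' @exportClass UnfoldingParams
setClass("UnfoldingParams",
  representation(tm0 = "numeric", dhVH = "numeric",
                 aN = "numeric", bN = "numeric",
                 aU = "numeric", bU = "numeric", noiseSd = "numeric"),
  prototype(tm0 = 57.6, dhVH = 5e5, aN = 10, bN = 0.05,
            aU = 110, bU = -0.2, noiseSd = 1.7))

setValidity("UnfoldingParams", function(object) {
  msg <- character()
  if (!(object@dhVH > 0)) msg <- c(msg, "dhVH must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!(object@aU > object@aN))
    msg <- c(msg, "aU must exceed aN (fluorescence rises on unfolding)")
  if (length(msg)) msg else TRUE
})

UnfoldingParams <- function(tm0 = 57.6, dhVH = 5e5, aN = 10, bN = 0.05,
                            aU = 110, bU = -0.2, noiseSd = 1.7) {
  new("UnfoldingParams", tm0 = tm0, dhVH = dhVH, aN = aN, bN = bN,
      aU = aU, bU = bU, noiseSd = noiseSd)
}

#' @rdname UnfoldingParams-class
#' @param x an \code{UnfoldingParams}
#' @export
tm0 <- function(x) x@tm0

#' Ligand binding to the folded state
#'
#' A ligand that binds the natively folded protein with dissociation
#' constant \code{kd} and is present at total concentration \code{conc}
#' (both mM). Folded-state binding depletes the unfolding-competent
#' population and raises the apparent midpoint with increasing
#' \code{conc/kd}; see \code{\link{shiftedTm}}. Appreciable shifts require
#' concentrations well above \code{kd}.
#'
#' @slot name character(1)
#' @slot kd numeric(1), mM, > 0
#' @slot conc numeric(1), mM, >= 0
#'
#' @param name,kd,conc see slots
#' @aliases LigandSpec
#' @export LigandSpec
#' @exportClass LigandSpec
setClass("LigandSpec",
  representation(name = "character", kd = "numeric", conc = "numeric"))

setValidity("LigandSpec", function(object) {
  msg <- character()
  if (!(object@kd > 0)) msg <- c(msg, "kd must be > 0")
  if (object@conc < 0) msg <- c(msg, "conc must be >= 0")
  if (length(msg)) msg else TRUE
})

LigandSpec <- function(name, kd, conc) {
  new("LigandSpec", name = as.character(name), kd = kd, conc = conc)
}

#' One buffer condition (arm) of a scenario
#'
#' A set of compounds screened under a common buffer condition (pH and ion
#' composition). Each compound is encoded either as its true temperature
#' shift in degrees C (a single number; how screen fixtures are normally
#' written, since screens report shifts, not affinities) or as a
#' \linkS4class{LigandSpec}, in which case the shift follows from the
#' binding thermodynamics.
#'
#' @slot ph numeric(1) buffer pH
#' @slot ions named numeric, ion concentrations in mM (e.g. c(Na = 140))
#' @slot concMM numeric(1), screening concentration of the compounds (mM),
#'   recorded in the sample sheet
#' @slot compounds named list; each element numeric(1) (true delta-Tm, degC)
#'   or a \code{LigandSpec}
#'
#' @param ph,ions,concMM,compounds see slots
#' @aliases ConditionArm
#' @export ConditionArm
#' @exportClass ConditionArm
setClass("ConditionArm",
  representation(ph = "numeric", ions = "numeric", concMM = "numeric",
                 compounds = "list"),
  prototype(ph = 7.0, ions = c(Na = 50), concMM = 2.5))

setValidity("ConditionArm", function(object) {
  msg <- character()
  nm <- names(object@compounds)
  if (length(object@compounds)) {
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
      msg <- c(msg, "compound names must be unique and non-empty")
    ok <- vapply(object@compounds, function(x)
      (is.numeric(x) && length(x) == 1L) || is(x, "LigandSpec"), logical(1))
    if (!all(ok))
      msg <- c(msg, "each compound must be numeric(1) or a LigandSpec")
  }
  if (length(object@ions) && is.null(names(object@ions)))
    msg <- c(msg, "ions must be a named numeric vector")
  if (length(msg)) msg else TRUE
})

ConditionArm <- function(compounds, ph = 7.0, ions = c(Na = 50),
                         concMM = 2.5) {
  new("ConditionArm", ph = ph, ions = ions, concMM = concMM,
      compounds = compounds)
}

#' Named synthetic screening scenario
#'
#' Full description of a simulated thermostability screen: the apo
#' unfolding parameters, one or more buffer-condition arms each with its
#' compound panel, and the replicate structure. Each biological repeat of
#' each arm becomes one instrument run holding \code{nTechControls}
#' no-ligand control wells plus one test well per compound; a run-level
#' jitter on the apo midpoint (default sd 0.3 degrees C, the scale of the
#' replicate scatter reported for such assays) models batch-to-batch
#' variation of independent protein preparations.
#'
#' @slot name,protein character(1)
#' @slot apo an \linkS4class{UnfoldingParams}
#' @slot arms named list of \linkS4class{ConditionArm}
#' @slot nBioReps integer(1) >= 3 biological repeats (independent runs)
#' @slot nTechControls integer(1) >= 1 control wells per run
#' @slot program a \linkS4class{TemperatureProgram}
#' @slot jitterSd numeric(1), sd of the per-run midpoint jitter (degrees C)
#'
#' @param name,protein,apo,arms,nBioReps,nTechControls,program,jitterSd see
#'   slots
#' @aliases ScenarioSpec
#' @export ScenarioSpec
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(name = "character", protein = "character",
                 apo = "UnfoldingParams", arms = "list",
                 nBioReps = "integer", nTechControls = "integer",
                 program = "TemperatureProgram", jitterSd = "numeric"))

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (object@nBioReps < 3L) msg <- c(msg, "nBioReps must be >= 3")
  if (object@nTechControls < 1L) msg <- c(msg, "nTechControls must be >= 1")
  if (!length(object@arms)) msg <- c(msg, "at least one condition arm")
  nm <- names(object@arms)
  if (length(object@arms) &&
      (is.null(nm) || any(nm == "") || anyDuplicated(nm)))
    msg <- c(msg, "arms must be uniquely named")
  if (!all(vapply(object@arms, is, logical(1), class2 = "ConditionArm")))
    msg <- c(msg, "arms must be ConditionArm objects")
  if (length(msg)) msg else TRUE
})

ScenarioSpec <- function(name, protein, apo, arms, nBioReps = 3L,
                         nTechControls = 3L,
                         program = TemperatureProgram(), jitterSd = 0.3) {
  if (is(arms, "ConditionArm")) arms <- list(base = arms)
  new("ScenarioSpec", name = name, protein = protein, apo = apo,
      arms = arms, nBioReps = as.integer(nBioReps),
      nTechControls = as.integer(nTechControls), program = program,
      jitterSd = jitterSd)
}

setMethod("show", "ScenarioSpec", function(object) {
  nc <- vapply(object@arms, function(a) length(a@compounds), integer(1))
  cat(sprintf(
    "ScenarioSpec '%s' (%s): %d arm(s), %s compounds, %d bio reps x %d controls\n",
    object@name, object@protein, length(object@arms),
    paste(nc, collapse = "+"), object@nBioReps, object@nTechControls))
})

#' Apparent-Tm call for one well
#'
#' Result of the derivative-peak Tm determination: the apparent melting
#' temperature (the peak of the smoothed dF/dT, refined below grid
#' resolution), the peak height, the fraction of the total signal range
#' attributable to the transition, QC flags, and the derivative trace used.
#'
#' QC flags: \code{no_transition} (transition rise below the amplitude
#' threshold), \code{edge_peak} (derivative maximum within 2 grid points of
#' either end of the ramp), \code{multi_peak} (a secondary derivative peak
#' at least 5 degrees C away reaching 60\% of the main peak). Flagged calls
#' carry a Tm but are excluded from screen statistics by default.
#'
#' @slot wellId,runId character(1)
#' @slot tm numeric(1), apparent Tm (degrees C)
#' @slot peakHeight numeric(1), dF/dT at the peak (AU/degC)
#' @slot amplitudeRatio numeric(1), transition rise / total signal range
#' @slot flags character, possibly empty
#' @slot derivative two-column matrix (temperature_C, dFdT)
#'
#' @param x a \code{TmCall}
#' @aliases TmCall
#' @exportClass TmCall
setClass("TmCall",
  representation(wellId = "character", runId = "character", tm = "numeric",
                 peakHeight = "numeric", amplitudeRatio = "numeric",
                 flags = "character", derivative = "matrix"))

setValidity("TmCall", function(object) {
  msg <- character()
  known <- c("no_transition", "edge_peak", "multi_peak", "low_amplitude")
  if (!all(object@flags %in% known))
    msg <- c(msg, "unknown QC flag")
  if (length(msg)) msg else TRUE
})

#' @rdname TmCall-class
#' @export
setMethod("tmValue", "TmCall", function(x) x@tm)
#' @rdname TmCall-class
#' @export
setMethod("qcFlags", "TmCall", function(x) x@flags)
#' @rdname TmCall-class
#' @export
setMethod("wellId", "TmCall", function(x) x@wellId)
#' @rdname TmCall-class
#' @export
setMethod("runId", "TmCall", function(x) x@runId)

setMethod("show", "TmCall", function(object) {
  cat(sprintf("TmCall %s/%s: Tm = %.2f degC, peak %.3g AU/degC%s\n",
              object@runId, object@wellId, object@tm, object@peakHeight,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

#' Screen report
#'
#' One record per (protein, compound, condition): the per-repeat
#' control-subtracted temperature shifts, their mean and sd, the number of
#' usable biological repeats, the p-value against the null of zero shift,
#' and its star classification. \code{records()} returns the underlying
#' data.frame (with list-columns \code{per_rep_delta} and
#' \code{excluded_wells}); \code{reportMetadata()} the provenance list.
#'
#' @slot records data.frame
#' @slot metadata list (program, options, seed provenance)
#'
#' @aliases ScreenReport
#' @exportClass ScreenReport
setClass("ScreenReport",
  representation(records = "data.frame", metadata = "list"))

ScreenReport <- function(records, metadata = list()) {
  new("ScreenReport", records = records, metadata = metadata)
}

#' @rdname ScreenReport-class
#' @export
setMethod("records", "ScreenReport", function(x) x@records)
#' @rdname ScreenReport-class
#' @export
setMethod("reportMetadata", "ScreenReport", function(x) x@metadata)

setMethod("show", "ScreenReport", function(object) {
  r <- object@records
  cat(sprintf("ScreenReport: %d records, %d protein(s), %d condition(s)\n",
              nrow(r), length(unique(r$protein)),
              length(unique(r$condition))))
  if (nrow(r)) {
    top <- utils::head(r[order(-r$mean_delta_tm_C), setdiff(
      names(r), c("per_rep_delta", "excluded_wells"))], 5L)
    print(top, row.names = FALSE)
  }
})
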