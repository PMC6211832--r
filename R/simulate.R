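#' Fraction of protein unfolded at a temperature
#'
#' Two-state equilibrium with temperature-independent van't Hoff enthalpy
#' (heat-capacity change neglected):
#' \deqn{\Delta G(T) = \Delta H_{vH} (1 - T/T_m), \quad
#'       K = e^{-\Delta G / RT}, \quad f_u = K/(1+K)}
#' with absolute temperatures. \code{fractionUnfolded} is continuous,
#' strictly increasing in \code{T}, and exactly 1/2 at
#' \code{effectiveTm} (where \eqn{\Delta G = 0} forces \eqn{K = 1}).
#'
#' @param T temperature(s), degrees C
#' @param params an \linkS4class{UnfoldingParams} (supplies the enthalpy)
#' @param effectiveTm midpoint to use, degrees C; defaults to the apo
#'   midpoint, and is raised by ligand binding (see \code{\link{shiftedTm}})
#' @return fraction unfolded in [0, 1], same length as \code{T}
#' @examples
#' p <- UnfoldingParams(tm0 = 57.6, dhVH = 4e5)
#' fractionUnfolded(57.6, p)        # exactly 0.5
#' fractionUnfolded(c(55, 60), p)
#' @export
fractionUnfolded <- function(T, params, effectiveTm = tm0(params)) {
  stopifnot(is(params, "UnfoldingParams"))
  validObject(params)
  tK <- T + .KELVIN
  tmK <- effectiveTm + .KELVIN
  dG <- params@dhVH * (1 - tK / tmK)
  K <- exp(-dG / (.RGAS * tK))
  K / (1 + K)
}

#' Ligand-shifted apparent midpoint
#'
#' Binding of a ligand to the folded state adds the binding free energy
#' \eqn{RT \ln(1 + [L]/K_d)} to the work of unfolding; the apparent
#' midpoint is the temperature at which the total free energy of unfolding
#' vanishes:
#' \deqn{\Delta H_{vH}(1 - T^*/T_{m0}) + R T^* \ln(1 + [L]/K_d) = 0.}
#' The root is bracketed in [tm0, tm0 + 40] and solved numerically. The
#' shift is zero at zero concentration, strictly increasing in
#' \code{conc/kd}, and vanishes as \code{kd} grows at fixed concentration:
#' appreciable shifts need concentrations well above the dissociation
#' constant.
#'
#' @param params an \linkS4class{UnfoldingParams}
#' @param ligand a \linkS4class{LigandSpec}
#' @return shifted midpoint, degrees C
#' @examples
#' p <- UnfoldingParams(tm0 = 57.6, dhVH = 4e5)
#' shiftedTm(p, LigandSpec("ADP", kd = 0.025, conc = 2.5))
#' @export
shiftedTm <- function(params, ligand) {
  stopifnot(is(params, "UnfoldingParams"), is(ligand, "LigandSpec"))
  if (ligand@conc > 0 && ligand@kd <= 0)
    stop("parameter error: ligand with conc > 0 requires kd > 0",
         call. = FALSE)
  validObject(params); validObject(ligand)
  if (ligand@conc == 0) return(params@tm0)
  bind <- log1p(ligand@conc / ligand@kd)
  g <- function(Tc) {
    tK <- Tc + .KELVIN
    params@dhVH * (1 - tK / (params@tm0 + .KELVIN)) + .RGAS * tK * bind
  }
  hi <- params@tm0 + 40
  if (g(hi) > 0)
    stop("model error: shifted midpoint not bracketed within [tm0, tm0 + 40]",
         call. = FALSE)
  stats::uniroot(g, lower = params@tm0, upper = hi, tol = 1e-9)$root
}

# Noiseless signal model: linear native/unfolded baselines mixed by the
# fraction unfolded at the effective midpoint.
.meltSignal <- function(Tg, params, effectiveTm) {
  f <- fractionUnfolded(Tg, params, effectiveTm)
  (params@aN + params@bN * Tg) * (1 - f) +
    (params@aU + params@bU * Tg) * f
}

#' Simulate one melt curve
#'
#' Generates \eqn{F(T) = (a_n + b_n T)(1 - f_u) + (a_u + b_u T) f_u +
#' \epsilon} on the program grid, with independent Gaussian noise per
#' reading. If a ligand is given, the midpoint is moved to
#' \code{\link{shiftedTm}}. Reproducible for a fixed seed.
#'
#' @param params an \linkS4class{UnfoldingParams}
#' @param ligand optional \linkS4class{LigandSpec}
#' @param program a \linkS4class{TemperatureProgram}
#' @param seed integer seed
#' @param wellId,runId labels for the resulting curve
#' @return a \linkS4class{MeltCurve}
#' @examples
#' cv <- simulateCurve(UnfoldingParams(), seed = 7)
#' cv
#' @export
simulateCurve <- function(params, ligand = NULL,
                          program = TemperatureProgram(), seed = 1L,
                          wellId = "A1", runId = "run1") {
  effTm <- if (is.null(ligand)) params@tm0 else shiftedTm(params, ligand)
  withLocalSeed(seed, {
    Tg <- programGrid(program)
    F <- .meltSignal(Tg, params, effTm)
    if (params@noiseSd > 0)
      F <- F + stats::rnorm(length(Tg), 0, params@noiseSd)
    MeltCurve(wellId, Tg, F, runId = runId)
  })
}

# Effective midpoint of one scenario compound entry relative to apo tm0.
.compoundShift <- function(entry, apo) {
  if (is(entry, "LigandSpec")) shiftedTm(apo, entry) - apo@tm0
  else as.numeric(entry)
}

#' Simulate a full screening scenario
#'
#' Expands a \linkS4class{ScenarioSpec} into melt curves plus the matching
#' sample sheet. Each (condition arm, biological repeat) pair becomes one
#' instrument run: a per-run jitter drawn from N(0, jitterSd) moves the apo
#' midpoint (independent protein batches), then \code{nTechControls}
#' control wells and one test well per compound are simulated on that run's
#' baseline. Compounds encoded as a number get that true temperature shift;
#' compounds encoded as a \linkS4class{LigandSpec} get the thermodynamic
#' shift from \code{\link{shiftedTm}}. Fully reproducible for a fixed seed.
#'
#' @param spec a \linkS4class{ScenarioSpec} (or the name of a built-in one,
#'   see \code{\link{builtinScenarios}})
#' @param seed integer seed
#' @return a list with elements \code{curves} (a
#'   \linkS4class{MeltCurveSet}) and \code{samples} (sample-sheet
#'   data.frame)
#' @examples
#' sim <- simulateScenario(builtinScenarios()[["galp"]], seed = 42)
#' length(sim$curves)
#' @export
simulateScenario <- function(spec, seed = 1L) {
  if (is.character(spec)) spec <- .resolveScenario(spec)
  stopifnot(is(spec, "ScenarioSpec"))
  validObject(spec)
  for (arm in spec@arms) validObject(arm)
  Tg <- programGrid(spec@program)
  curves <- list()
  rows <- list()
  withLocalSeed(seed, {
    for (armName in names(spec@arms)) {
      arm <- spec@arms[[armName]]
      shifts <- vapply(arm@compounds, .compoundShift, numeric(1),
                       apo = spec@apo)
      for (rep in seq_len(spec@nBioReps)) {
        run <- sprintf("%s_%s_R%d", spec@name, armName, rep)
        jit <- if (spec@jitterSd > 0) stats::rnorm(1, 0, spec@jitterSd)
               else 0
        base <- spec@apo@tm0 + jit
        emit <- function(well, effTm, compound, conc, role) {
          F <- .meltSignal(Tg, spec@apo, effTm)
          if (spec@apo@noiseSd > 0)
            F <- F + stats::rnorm(length(Tg), 0, spec@apo@noiseSd)
          curves[[length(curves) + 1L]] <<-
            MeltCurve(well, Tg, F, runId = run)
          rows[[length(rows) + 1L]] <<- data.frame(
            run_id = run, well_id = well, protein = spec@protein,
            compound = compound, concentration_mM = conc, ph = arm@ph,
            ions = formatIons(arm@ions), role = role, bio_rep = rep,
            stringsAsFactors = FALSE)
        }
        for (i in seq_len(spec@nTechControls))
          emit(sprintf("C%d", i), base, "", 0, "control")
        for (j in seq_along(shifts))
          emit(sprintf("S%02d", j), base + shifts[[j]],
               names(shifts)[j], arm@concMM, "test")
      }
    }
  })
  list(curves = MeltCurveSet(curves),
       samples = validateSampleSheet(do.call(rbind, rows)))
}
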