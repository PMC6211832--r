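# Shared fixture builders; everything is generated in code at test time.

# Noiseless two-state signal on an explicit grid (independent of the
# package's internal generator beyond the shared closed form).
twoStateSignal <- function(Tg, tm, dh = 4e5, aN = 10, bN = 0, aU = 110,
                           bU = 0) {
  K <- exp((dh / 8.314) * (1 / (tm + 273.15) - 1 / (Tg + 273.15)))
  f <- K / (1 + K)
  (aN + bN * Tg) * (1 - f) + (aU + bU * Tg) * f
}

# Dense-grid oracle for the derivative-peak temperature of the noiseless
# signal: brute-force argmax of finite differences on a 1e-4 degC grid.
densePeakOracle <- function(tm, dh = 4e5, aN = 10, bN = 0, aU = 110,
                            bU = 0, lo = 25, hi = 90) {
  Tg <- seq(max(lo, tm - 12), min(hi, tm + 12), by = 1e-4)
  F <- twoStateSignal(Tg, tm, dh, aN, bN, aU, bU)
  mid <- (Tg[-1] + Tg[-length(Tg)]) / 2
  mid[which.max(diff(F) / diff(Tg))]
}

# Minimal two-run screen fixture built directly from Tm-call and
# sample-sheet data frames (bypasses curve simulation).
makeCallFixture <- function(ctrlTm = list(c(57.5, 57.7, 57.6),
                                          c(57.4, 57.6, 57.5)),
                            testTm = list(A = c(63.3, 63.1),
                                          B = c(55.6, 55.5)),
                            flags = NULL) {
  runs <- paste0("R", seq_along(ctrlTm))
  calls <- list(); samp <- list()
  for (i in seq_along(runs)) {
    for (j in seq_along(ctrlTm[[i]])) {
      calls[[length(calls) + 1]] <- data.frame(
        run_id = runs[i], well_id = paste0("C", j), tm = ctrlTm[[i]][j],
        peak_height = 10, amplitude_ratio = 0.9, flags = "")
      samp[[length(samp) + 1]] <- data.frame(
        run_id = runs[i], well_id = paste0("C", j), protein = "P",
        compound = "", concentration_mM = 0, ph = 7, ions = "Na=50",
        role = "control", bio_rep = i)
    }
    for (cp in names(testTm)) {
      calls[[length(calls) + 1]] <- data.frame(
        run_id = runs[i], well_id = paste0("S_", cp),
        tm = testTm[[cp]][i], peak_height = 10, amplitude_ratio = 0.9,
        flags = "")
      samp[[length(samp) + 1]] <- data.frame(
        run_id = runs[i], well_id = paste0("S_", cp), protein = "P",
        compound = cp, concentration_mM = 2.5, ph = 7, ions = "Na=50",
        role = "test", bio_rep = i)
    }
  }
  calls <- do.call(rbind, calls)
  if (!is.null(flags))
    for (k in names(flags))
      calls$flags[paste(calls$run_id, calls$well_id) == k] <- flags[[k]]
  list(calls = calls, samples = do.call(rbind, samp))
}

# Small null scenario used by the calibration tests.
nullScenario <- function(nCompounds = 10, nReps = 3) {
  comp <- setNames(as.list(rep(0, nCompounds)),
                   sprintf("cmpd%02d", seq_len(nCompounds)))
  ScenarioSpec(name = "null", protein = "P",
               apo = UnfoldingParams(tm0 = 56),
               arms = list(base = ConditionArm(comp)),
               nBioReps = nReps)
}
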