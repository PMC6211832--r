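p400 <- UnfoldingParams(tm0 = 57.6, dhVH = 4e5)

test_that("fraction unfolded matches the closed form and its limits", {
  # frozen values from an independent evaluation of the van't Hoff form
  expect_equal(fractionUnfolded(55, p400), 0.24002784342399866,
               tolerance = 1e-12)
  expect_equal(fractionUnfolded(60, p400), 0.74037222711200430,
               tolerance = 1e-12)
  # midpoint is exactly one half (Delta G = 0 forces K = 1)
  expect_identical(fractionUnfolded(57.6, p400), 0.5)
  expect_identical(fractionUnfolded(70, p400, effectiveTm = 70), 0.5)
  # limits
  expect_lt(fractionUnfolded(10, p400), 1e-8)
  expect_gt(fractionUnfolded(95, p400), 1 - 1e-6)
})

test_that("fraction unfolded is strictly increasing onto (0,1)", {
  for (dh in c(2e5, 4e5, 6e5)) {
    p <- UnfoldingParams(tm0 = 50, dhVH = dh)
    f <- fractionUnfolded(seq(25, 90, by = 0.25), p)
    expect_true(all(diff(f) > 0))
    expect_true(all(f > 0 & f < 1))
  }
})

test_that("ligand-shifted midpoint matches the bisection oracle", {
  # frozen values from an independent bisection on
  # dH (1 - T/Tm0) + R T ln(1 + conc/kd) = 0
  expect_equal(shiftedTm(p400, LigandSpec("x", kd = 0.025, conc = 2.5)),
               68.4376491552982, tolerance = 1e-6)
  expect_equal(shiftedTm(p400, LigandSpec("x", kd = 0.025, conc = 0.25)),
               63.1436883777944, tolerance = 1e-6)
  # no ligand, no shift; huge kd, vanishing shift
  expect_identical(shiftedTm(p400, LigandSpec("x", kd = 1, conc = 0)), 57.6)
  expect_lt(shiftedTm(p400, LigandSpec("x", kd = 1e7, conc = 1)) - 57.6,
            1e-4)
  expect_error(shiftedTm(p400, LigandSpec("x", kd = 1e-9, conc = 1e9)),
               "not bracketed")
})

test_that("shift grows monotonically with concentration", {
  concs <- 10^seq(-3, 2, length.out = 12)
  shifts <- vapply(concs, function(cc)
    shiftedTm(p400, LigandSpec("x", kd = 0.025, conc = cc)) - 57.6,
    numeric(1))
  expect_true(all(diff(shifts) > 0))
  expect_true(all(shifts > 0))
})

test_that("simulated curves are reproducible and hit the noiseless midpoint", {
  c1 <- simulateCurve(p400, seed = 7)
  c2 <- simulateCurve(p400, seed = 7)
  expect_identical(fluorescence(c1), fluorescence(c2))
  expect_false(identical(fluorescence(c1),
                         fluorescence(simulateCurve(p400, seed = 8))))

  # flat baselines, zero noise: F at the midpoint is the plateau average
  flat <- UnfoldingParams(tm0 = 57.6, dhVH = 4e5, bN = 0, bU = 0,
                          noiseSd = 0)
  prog <- TemperatureProgram(25.6, 90.6, 1)  # grid containing 57.6
  cv <- simulateCurve(flat, program = prog, seed = 1)
  expect_equal(fluorescence(cv)[temperatures(cv) == 57.6], (10 + 110) / 2,
               tolerance = 1e-9)

  # zero-concentration ligand leaves the curve untouched at equal seed
  lig0 <- LigandSpec("x", kd = 0.025, conc = 0)
  expect_identical(fluorescence(simulateCurve(p400, lig0, seed = 3)),
                   fluorescence(simulateCurve(p400, seed = 3)))
})

test_that("scenario simulation has the declared plate structure", {
  sc <- builtinScenarios()[["galp"]]
  sim <- simulateScenario(sc, seed = 42)
  expect_length(sim$curves, 70)  # 5 runs x (3 controls + 11 compounds)
  expect_equal(nrow(sim$samples), 70)
  expect_equal(length(unique(sim$samples$run_id)), 5)
  expect_equal(sum(sim$samples$role == "control"), 15)

  sim2 <- simulateScenario(sc, seed = 42)
  expect_identical(lapply(as.list(sim2$curves), fluorescence),
                   lapply(as.list(sim$curves), fluorescence))
  expect_identical(sim2$samples, sim$samples)
})

test_that("an exact null scenario yields exactly zero shifts end to end", {
  sc <- nullScenario(nCompounds = 4)
  sc@apo@noiseSd <- 0
  sc@jitterSd <- 0
  sim <- simulateScenario(sc, seed = 1)
  calls <- callTmSet(sim$curves)
  deltas <- computeDeltaTm(calls, sim$samples)
  expect_equal(deltas$delta_tm, rep(0, nrow(deltas)), tolerance = 1e-9)
})

test_that("scenario YAML serialization round-trips", {
  sc <- builtinScenarios()[["tt_pic_ph"]]
  path <- tempfile(fileext = ".yaml")
  writeScenario(sc, path)
  back <- readScenario(path)
  expect_equal(back@name, sc@name)
  expect_equal(back@nBioReps, sc@nBioReps)
  expect_equal(names(back@arms), names(sc@arms))
  expect_equal(back@arms$ph8@compounds, sc@arms$ph8@compounds)
  expect_equal(back@apo@tm0, sc@apo@tm0)
  # simulation from the round-tripped spec is bit-identical
  a <- simulateScenario(sc, seed = 5)
  b <- simulateScenario(back, seed = 5)
  expect_identical(lapply(as.list(a$curves), fluorescence),
                   lapply(as.list(b$curves), fluorescence))
})

test_that("built-in fixtures encode the published ground truth", {
  sc <- builtinScenarios()
  expect_length(sc$tt_pic@arms$base@compounds, 132)
  expect_equal(sc$galp@apo@tm0, 57.6)
  expect_equal(sc$mhp1@apo@tm0, 51.3)
  expect_equal(sc$tt_pic@arms$base@compounds[["phosphate"]], 4.6)
  expect_equal(sc$galp@arms$base@compounds[["D-glucosamine"]], 5.7)
  expect_equal(sc$mhp1@arms$base@compounds[["L-NMH"]], 15.6)
  expect_equal(sc$aac@arms$base@compounds[["ATP"]], 7.2)
  expect_equal(sc$tt_pic_ph@arms$ph6@compounds[["phosphate"]], 4.6)
  expect_equal(sc$tt_pic_ph@arms$ph8@compounds[["phosphate"]], 2.6)
  # every L-isoform decoy in the sugar screen is truly null
  galp <- sc$galp@arms$base@compounds
  decoys <- galp[grepl("^L-", names(galp))]
  expect_true(all(unlist(decoys) == 0))
})
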