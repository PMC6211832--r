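test_that("run control Tm is the mean of unflagged control calls", {
  fx <- makeCallFixture(ctrlTm = list(c(57.5, 57.7, 57.6)),
                        testTm = list(A = 63.3))
  ctrl <- runControlTm(fx$calls, fx$samples)
  expect_equal(ctrl$control_tm, 57.6)
  expect_equal(ctrl$n_controls, 3)

  # flagged control drops out of the average
  fx2 <- makeCallFixture(ctrlTm = list(c(57.5, 57.7, 50.0)),
                         testTm = list(A = 63.3),
                         flags = list("R1 C3" = "no_transition"))
  expect_equal(runControlTm(fx2$calls, fx2$samples)$control_tm, 57.6)

  # all controls flagged: the run is unusable
  fx3 <- makeCallFixture(ctrlTm = list(c(57.5, 57.7)),
                         testTm = list(A = 63.3),
                         flags = list("R1 C1" = "no_transition",
                                      "R1 C2" = "edge_peak"))
  expect_error(suppressWarnings(runControlTm(fx3$calls, fx3$samples)),
               "no run has a usable control")
})

test_that("delta Tm is signed and flagged test wells are excluded", {
  fx <- makeCallFixture(ctrlTm = list(c(57.5, 57.7, 57.6)),
                        testTm = list(A = 63.3, B = 55.6))
  d <- computeDeltaTm(fx$calls, fx$samples)
  expect_equal(d$delta_tm[d$compound == "A"], 5.7)
  expect_equal(d$delta_tm[d$compound == "B"], -2.0)

  fx2 <- makeCallFixture(ctrlTm = list(c(57.5, 57.7, 57.6)),
                         testTm = list(A = 63.3, B = 55.6),
                         flags = list("R1 S_B" = "edge_peak"))
  d2 <- computeDeltaTm(fx2$calls, fx2$samples)
  expect_false("B" %in% d2$compound)
  exc <- attr(d2, "excluded")
  expect_equal(exc$compound, "B")
  expect_equal(exc$flags, "edge_peak")
})

test_that("delta Tm is invariant to a common temperature offset", {
  fx <- makeCallFixture()
  d0 <- computeDeltaTm(fx$calls, fx$samples)
  fx$calls$tm <- fx$calls$tm + 3.21
  d1 <- computeDeltaTm(fx$calls, fx$samples)
  expect_equal(d1$delta_tm, d0$delta_tm, tolerance = 1e-12)
})

test_that("Welch test matches the direct Satterthwaite formulas", {
  # frozen oracle for the canonical example
  res <- welchTTest(c(63.2, 63.4, 63.3), c(57.5, 57.7, 57.6))
  expect_equal(res$t, 69.81045766932077, tolerance = 1e-10)
  expect_equal(res$df, 4.0, tolerance = 1e-10)
  expect_equal(res$p, 2.5227571941284514e-07, tolerance = 1e-8)
  expect_lt(res$p, 0.01)

  # brute-force evaluation on random pairs
  set.seed(99)
  for (i in 1:100) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- rnorm(nx, 0, runif(1, 0.5, 3))
    y <- rnorm(ny, runif(1, -2, 2), runif(1, 0.5, 3))
    got <- welchTTest(x, y)
    sx <- var(x) / nx; sy <- var(y) / ny
    tt <- (mean(x) - mean(y)) / sqrt(sx + sy)
    df <- (sx + sy)^2 / (sx^2 / (nx - 1) + sy^2 / (ny - 1))
    p <- 2 * pt(-abs(tt), df)
    expect_equal(got$t, tt, tolerance = 1e-10)
    expect_equal(got$df, df, tolerance = 1e-10)
    expect_equal(got$p, p, tolerance = 1e-10)
  }
})

test_that("Welch degenerate inputs are resolved explicitly", {
  expect_equal(welchTTest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welchTTest(c(1, 2, 3), c(3, 2, 1))$p, 1)
  expect_equal(welchTTest(c(2, 2), c(2, 2))$p, 1)
  expect_lt(welchTTest(c(2, 2), c(3, 3))$p, 1e-300)
  expect_error(welchTTest(c(1, 2), 1), "at least 2")
})

test_that("star classification follows the screening convention", {
  expect_equal(classifySignificance(c(0.03, 0.2, 5e-6, 5e-4, 5e-3)),
               c("*", "ns", "****", "***", "**"))
  # boundaries go to the less significant class
  expect_equal(classifySignificance(c(0.05, 0.01, 1e-3, 1e-4, 1)),
               c("ns", "*", "**", "***", "ns"))
  expect_error(classifySignificance(0), "0, 1")
  expect_error(classifySignificance(1.2), "0, 1")
})

test_that("screen aggregation yields one record per compound with stars", {
  fx <- makeCallFixture(
    ctrlTm = list(c(57.5, 57.7, 57.6), c(57.4, 57.6, 57.5),
                  c(57.6, 57.8, 57.7)),
    testTm = list(A = c(63.3, 63.2, 63.4), B = c(57.7, 57.5, 57.8)))
  rep <- aggregateScreen(fx$calls, fx$samples)
  r <- records(rep)
  expect_equal(nrow(r), 2)
  expect_equal(r$n, c(3, 3))
  expect_equal(r$mean_delta_tm_C[r$compound == "A"],
               mean(c(63.3 - 57.6, 63.2 - 57.5, 63.4 - 57.7)))
  expect_true(r$stars[r$compound == "A"] != "ns")
  expect_equal(r$stars[r$compound == "B"], "ns")
  # per-record consistency between the list column and the summaries
  for (i in seq_len(nrow(r))) {
    expect_equal(mean(r$per_rep_delta[[i]]), r$mean_delta_tm_C[i])
    expect_equal(sd(r$per_rep_delta[[i]]), r$sd_delta_tm_C[i])
  }
})

test_that("fewer than two usable repeats gives NA p and ns stars", {
  fx <- makeCallFixture(ctrlTm = list(c(57.5, 57.7, 57.6)),
                        testTm = list(A = 63.3))
  r <- records(aggregateScreen(fx$calls, fx$samples))
  expect_true(is.na(r$p_value))
  expect_equal(r$stars, "ns")
  expect_equal(r$n, 1)
})

test_that("one-sample and two-sample forms reach the same call on hits", {
  sc <- builtinScenarios()[["aac"]]
  sc@jitterSd <- 0   # no batch effect: the two forms test the same null
  sim <- simulateScenario(sc, seed = 8)
  calls <- callTmSet(sim$curves)
  p1 <- records(aggregateScreen(calls, sim$samples, test = "one_sample"))
  p2 <- records(aggregateScreen(calls, sim$samples, test = "welch"))
  expect_equal(p1$compound, p2$compound)
  expect_equal(p1$mean_delta_tm_C, p2$mean_delta_tm_C)
  for (cp in c("ATP", "ADP", "dADP")) {
    expect_true(p1$stars[p1$compound == cp] != "ns")
    expect_true(p2$stars[p2$compound == cp] != "ns")
  }
})

test_that("hit ranking orders by shift with star threshold", {
  fx <- makeCallFixture(
    ctrlTm = list(c(50.0, 50.1, 49.9), c(50.1, 50.0, 50.2),
                  c(49.9, 50.0, 50.1)),
    testTm = list(big = c(60.0, 60.1, 59.9), mid = c(55.0, 55.1, 54.9),
                  null = c(50.05, 50.1, 50.0)))
  rep <- aggregateScreen(fx$calls, fx$samples)
  top <- rankHits(rep)
  expect_equal(top$compound[1:2], c("big", "mid"))
  # a stricter threshold can only shrink the list, and never admits ns
  # records however large their shift
  expect_true(all(rankHits(rep, "****")$compound %in% top$compound))
  expect_false("null" %in% rankHits(rep, "****")$compound)
  # empty selection yields an empty, well-formed table
  none <- rep
  none@records$stars <- "ns"
  expect_equal(nrow(rankHits(none, "*")), 0)
})

test_that("condition contrast subtracts shifts and propagates error", {
  res <- screenScenario("tt_pic_ph", seed = 11)
  cc <- conditionContrast(res$report, "pH6;Na=50", "pH8;Na=50")
  expect_equal(nrow(cc), 2)
  ph <- cc[cc$compound == "phosphate", ]
  expect_gt(ph$delta_delta_tm_C, 0)
  expect_equal(ph$delta_delta_tm_C, 2.0, tolerance = 0.5)
  # identical reports contrast to zero
  cc0 <- conditionContrast(res$report, "pH6;Na=50", "pH6;Na=50")
  expect_equal(cc0$delta_delta_tm_C, rep(0, 2))
})
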