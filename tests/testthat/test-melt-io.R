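test_that("wide and long dialects of the same plate parse identically", {
  Tg <- 25:90
  set.seed(11)
  f1 <- twoStateSignal(Tg, 55) + rnorm(66)
  f2 <- twoStateSignal(Tg, 60) + rnorm(66)
  wide <- tempfile(fileext = ".csv")
  write.csv(data.frame(temperature_C = Tg, A1 = f1, A2 = f2), wide,
            row.names = FALSE)
  long <- tempfile(fileext = ".csv")
  df <- rbind(data.frame(run_id = "run1", well = "A1", temperature_C = Tg,
                         fluorescence = f1),
              data.frame(run_id = "run1", well = "A2", temperature_C = Tg,
                         fluorescence = f2))
  df <- df[sample(nrow(df)), ]  # shuffled row order must not matter
  write.csv(df, long, row.names = FALSE)

  cw <- readMeltTable(wide, dialect = "wide")
  cl <- readMeltTable(long, dialect = "long")
  expect_s4_class(cw, "MeltCurveSet")
  expect_length(cw, 2)
  expect_length(cl, 2)
  for (i in 1:2) {
    expect_equal(temperatures(cl[[i]]), Tg)
    expect_equal(fluorescence(cl[[i]]), fluorescence(cw[[i]]))
    expect_equal(wellId(cl[[i]]), wellId(cw[[i]]))
  }
})

test_that("melt-table round trip through the long dialect is exact", {
  sim <- simulateScenario(builtinScenarios()[["aac"]], seed = 3)
  path <- tempfile(fileext = ".csv")
  writeMeltTable(sim$curves, path)
  back <- readMeltTable(path, dialect = "long")
  expect_length(back, length(sim$curves))
  orig <- as.list(sim$curves)
  key <- function(x) paste(runId(x), wellId(x))
  orig <- orig[order(vapply(orig, key, character(1)))]
  for (i in seq_along(orig)) {
    expect_equal(fluorescence(back[[i]]), fluorescence(orig[[i]]),
                 tolerance = 1e-12)
  }
})

test_that("melt-table errors name the problem", {
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(run_id = "r", well = "A1", temperature_C = 25:90),
            bad, row.names = FALSE)
  expect_error(readMeltTable(bad, "long"), "fluorescence")

  short <- tempfile(fileext = ".csv")
  write.csv(data.frame(run_id = "r", well = "A1", temperature_C = 25:29,
                       fluorescence = 1:5), short, row.names = FALSE)
  expect_error(readMeltTable(short, "long"), "fewer than 10 points")

  dup <- tempfile(fileext = ".csv")
  write.csv(data.frame(run_id = "r", well = "A1",
                       temperature_C = c(25:35, 30),
                       fluorescence = rep(1, 12)), dup, row.names = FALSE)
  expect_error(readMeltTable(dup, "long"), "duplicate")
})

test_that("sample sheets are validated against the annotation invariants", {
  sheet <- data.frame(
    run_id = "R1", well_id = c(paste0("C", 1:3), paste0("S", 1:9)),
    protein = "GalP",
    compound = c(rep("", 3), paste0("cmpd", 1:9)),
    concentration_mM = c(rep(0, 3), rep(50, 9)),
    ph = 7.5, ions = "Na=150",
    role = c(rep("control", 3), rep("test", 9)), bio_rep = 1L)
  path <- tempfile(fileext = ".csv")
  writeSampleSheet(sheet, path)
  ann <- readSampleSheet(path)
  expect_equal(nrow(ann), 12)
  expect_equal(sum(ann$role == "control"), 3)

  bad <- sheet; bad$compound[1] <- "ADP"
  expect_error(validateSampleSheet(bad), "control wells must have no")

  dup <- rbind(sheet, sheet[4, ])
  expect_error(validateSampleSheet(dup), "duplicate")

  noctrl <- sheet[sheet$role == "test", ]
  expect_error(validateSampleSheet(noctrl), "without control")

  badrole <- sheet; badrole$role[5] <- "blank"
  expect_error(validateSampleSheet(badrole), "role")
})

test_that("ion map encoding round-trips", {
  ions <- c(Na = 140, K = 5.5)
  expect_equal(meltscreen:::parseIons(meltscreen:::formatIons(ions)), ions)
  expect_length(meltscreen:::parseIons(""), 0)
  expect_error(meltscreen:::parseIons("Na140"), "malformed")
})

test_that("screen report TSV and JSON round-trip, stars match p-values", {
  fx <- makeCallFixture()
  rep0 <- aggregateScreen(fx$calls, fx$samples)
  r0 <- records(rep0)
  tsv <- tempfile(fileext = ".tsv")
  writeScreenReport(rep0, tsv, "tsv")
  rt <- records(readScreenReport(tsv, "tsv"))
  expect_equal(rt$compound, r0$compound)
  expect_equal(rt$mean_delta_tm_C, signif(r0$mean_delta_tm_C, 6))
  expect_equal(rt$stars, r0$stars)

  js <- tempfile(fileext = ".json")
  writeScreenReport(rep0, js, "json")
  rj <- records(readScreenReport(js, "json"))
  expect_equal(rj$mean_delta_tm_C, r0$mean_delta_tm_C, tolerance = 1e-12)
  expect_equal(rj$p_value, r0$p_value, tolerance = 1e-12)
  expect_equal(rj$per_rep_delta, lapply(r0$per_rep_delta, as.numeric),
               tolerance = 1e-12)
  # header + one row per record in the TSV
  expect_equal(length(readLines(tsv)), nrow(r0) + 1)
})
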