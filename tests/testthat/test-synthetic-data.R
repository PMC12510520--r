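test_that("OGTT curve sits at baseline before ingestion and peaks at time_to_peak", {
  p <- ogttParams(glucose_noise_sd = 0, duration_after = 200)
  curve <- ogttGlucoseCurve(p, seed = 1)
  pre <- curve$glucose_mg_dl[curve$time_min <= 0]
  expect_equal(pre, rep(p$baseline_glucose, length(pre)))
  expect_equal(curve$time_min[which.max(curve$glucose_mg_dl)], p$time_to_peak)
  expect_equal(max(curve$glucose_mg_dl),
               p$baseline_glucose + p$peak_excess)
  # excursion has largely decayed by 4x the time to peak
  at4tp <- curve$glucose_mg_dl[curve$time_min == 4 * p$time_to_peak]
  expect_lt(at4tp, p$baseline_glucose + 0.25 * p$peak_excess)
})

test_that("OGTT curve is reproducible from its seed and validates params", {
  p <- ogttParams()
  expect_identical(ogttGlucoseCurve(p, seed = 11), ogttGlucoseCurve(p, seed = 11))
  expect_false(identical(ogttGlucoseCurve(p, seed = 11),
                         ogttGlucoseCurve(p, seed = 12)))
  expect_error(ogttParams(sampling_interval = 0), "positive")
  expect_error(ogttParams(baseline_glucose = -90), "positive")
})

test_that("trailing moving average shortens leading windows", {
  expect_equal(trailingMovingAverage(c(90, 120, 150)), c(90, 105, 120))
  expect_equal(trailingMovingAverage(rep(7, 10)), rep(7, 10))
  x <- rnorm(20)
  expect_equal(trailingMovingAverage(x, 1L), x)
  # window longer than the series: running mean of everything so far
  expect_equal(trailingMovingAverage(c(2, 4, 6), 10L), c(2, 3, 4))
  expect_error(trailingMovingAverage(numeric()), "non-empty")
  expect_error(trailingMovingAverage(1:3, 0L), "window")
})

test_that("datasets are bit-identical for identical seeds and sized as requested", {
  ns <- noiseParams("fixed", seed = 21)
  d1 <- generateDataset(83, "fixed", noise = ns)
  d2 <- generateDataset(83, "fixed", noise = ns)
  expect_identical(spectraMatrix(d1), spectraMatrix(d2))
  expect_identical(glucoseRef(d1), glucoseRef(d2))
  expect_equal(ncol(d1), 83)
  # a 2-h window either side of ingestion at 5 min gives 49 records/day
  expect_identical(sort(unique(SummarizedExperiment::colData(d1)$day)), 1:2)
  d3 <- generateDataset(83, "fixed", noise = noiseParams("fixed", seed = 22))
  expect_false(identical(spectraMatrix(d1), spectraMatrix(d3)))
})

test_that("labels agree with the threshold rule on smoothed glucose", {
  ds <- generateDataset(83, "fixed", noise = noiseParams("fixed", seed = 5))
  expect_identical(classLabels(ds), labelByThreshold(glucoseSmoothed(ds)))
  expect_true(all(acquisitionMode(ds) == "fixed"))
  expect_error(generateDataset(0, noise = noiseParams("fixed")), "n_records")
  expect_error(generateDataset(5, noise = noiseParams("fixed"),
                               grid = seq(900, 1200, 2)), "930")
  expect_error(generateDataset(5, "repositioned", noise = noiseParams("fixed")),
               "mode")
})

test_that("higher glucose deepens the glucose-band dips, leaving other points unchanged", {
  grid <- defaultGrid()
  lo <- spectrumValues(synthesizePASSpectrum(skin_fixture(90), grid))
  hi <- spectrumValues(synthesizePASSpectrum(skin_fixture(180), grid))
  centres <- c(990, 1110)
  expect_true(all(hi[grid %in% centres] < lo[grid %in% centres]))
  # outside the glucose bands (> 5 sigma from both centres) spectra coincide
  outside <- abs(grid - 990) > 40 & abs(grid - 1110) > 40
  expect_equal(hi[outside], lo[outside])
})

test_that("repositioned acquisition is more variable than fixed", {
  point_sd <- function(mode, seed) {
    ns <- noiseParams(mode, seed = seed)
    mean(apply(spectraMatrix(generateDataset(40, mode, noise = ns)), 1, sd))
  }
  seeds <- 1:20
  sd_fixed <- vapply(seeds, function(s) point_sd("fixed", s), numeric(1))
  sd_repos <- vapply(seeds, function(s) point_sd("repositioned", s), numeric(1))
  expect_gt(mean(sd_repos), mean(sd_fixed))
})
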