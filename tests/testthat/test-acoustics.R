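test_that("acoustic wavelength is v/f", {
  expect_identical(acousticWavelength(1, 1), 1)
  expect_equal(acousticWavelength(1389, 520875), 2.667e-3, tolerance = 1e-3)
  expect_equal(acousticWavelength(1580, 503000), 3.141e-3, tolerance = 1e-3)
  expect_error(acousticWavelength(0, 100), "> 0")
  expect_error(acousticWavelength(1389, -1), "> 0")
})

test_that("quarter-wave resonances form the odd-harmonic family (2m+1)v/4t", {
  f2 <- resonanceFrequencies(gel2mm(), 1)
  expect_equal(f2$frequency_hz[f2$mode == 1], 520875)
  f4 <- resonanceFrequencies(gel4mm(), 2)
  expect_equal(f4$frequency_hz[f4$mode == 2], 434062.5)
  # fundamental is v/(4t)
  expect_equal(resonanceFrequencies(gel2mm(), 0)$frequency_hz,
               1389 / (4 * 2e-3))
  expect_error(resonanceFrequencies(gel2mm(), -1), "max_mode")
})

test_that("resonances scale exactly as 1/thickness with ratios 1:3:5:...", {
  f2 <- resonanceFrequencies(gel2mm(), 5)$frequency_hz
  f4 <- resonanceFrequencies(gel4mm(), 5)$frequency_hz
  expect_equal(f4, f2 / 2)
  expect_equal(f2 / f2[1], c(1, 3, 5, 7, 9, 11))
  expect_true(all(diff(f2) > 0))
})

test_that("impedance reflection coefficient matches the interface estimates", {
  expect_identical(reflectionCoefficient(1.6, 1.6), 0)
  expect_equal(reflectionCoefficient(4.6, 1.9), -0.4153846, tolerance = 1e-6)
  expect_equal(reflectionCoefficient(1.9, 1.6), -0.0857143, tolerance = 1e-5)
  expect_error(reflectionCoefficient(0, 1), "> 0")
})

test_that("reflection coefficient is antisymmetric and vanishes iff matched", {
  set.seed(42)
  z1 <- runif(50, 0.5, 10)
  z2 <- runif(50, 0.5, 10)
  r12 <- reflectionCoefficient(z1, z2)
  expect_equal(r12, -reflectionCoefficient(z2, z1))
  expect_true(all(abs(r12) < 1))
  expect_identical(which(r12 == 0), which(z1 == z2))
})

test_that("frequency response is baseline*(1+gain) on resonance, baseline far off", {
  layer <- gel2mm()
  f1 <- resonanceFrequencies(layer, 0)$frequency_hz  # 173.625 kHz
  sw <- frequencyResponse(layer, c(f1 / 10, f1), quality_factor = 200,
                          baseline = 2, resonance_gain = 3, max_mode = 0)
  amps <- sweepAmplitudes(sw)
  expect_equal(amps[2], 2 * (1 + 3))
  expect_equal(amps[1], 2, tolerance = 1e-3)
  # default gain 3 gives the observed on/off resonance amplitude ratio of ~4
  expect_equal(amps[2] / amps[1], 4, tolerance = 1e-2)
  expect_error(frequencyResponse(layer, numeric()), "non-empty")
})

test_that("peak finding recovers the analytic resonances of the gels", {
  freqs <- seq(4e5, 7e5, by = 500)
  p2 <- findResonancePeaks(frequencyResponse(gel2mm(), freqs,
                                             quality_factor = 40))
  expect_length(p2, 1)
  expect_lte(abs(p2 - 520875), 500)
  p4 <- findResonancePeaks(frequencyResponse(gel4mm(), freqs,
                                             quality_factor = 40))
  expect_length(p4, 2)
  expect_lte(abs(p4[1] - 434062.5), 500)
  expect_lte(abs(p4[2] - 607687.5), 500)
})

test_that("peak finding returns empty for ramps and flat sweeps", {
  f <- seq(1, 100)
  expect_identical(findResonancePeaks(FrequencySweep(f, f)), numeric())
  expect_identical(findResonancePeaks(FrequencySweep(f, rep(1, 100))),
                   numeric())
  expect_error(findResonancePeaks(FrequencySweep(f, f), 1.5),
               "prominence_fraction")
})

test_that("thickness estimation inverts the resonance condition", {
  expect_equal(estimateThickness(520875, 1389, 1), 2)
  expect_equal(estimateThickness(434062.5, 1389, 2), 4)
  expect_identical(round(estimateThickness(503000, 1580, 1), 2), 2.36)
  # exact round trip across modes and thicknesses
  for (t_mm in c(1, 2, 4, 7)) {
    layer <- AcousticLayer(t_mm, 1389)
    fr <- resonanceFrequencies(layer, 4)
    expect_equal(estimateThickness(fr$frequency_hz, 1389, fr$mode),
                 rep(t_mm, 5))
  }
  expect_error(estimateThickness(-1, 1389, 0), "> 0")
})
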