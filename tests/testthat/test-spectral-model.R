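test_that("effective absorption coefficient is the water-weighted coefficient", {
  expect_identical(effectiveAbsorption(1.0, 817), 817)
  expect_equal(effectiveAbsorption(0.3, 817), 245.1)
  expect_equal(effectiveAbsorption(0.1, 817), 81.7)
  expect_error(effectiveAbsorption(-0.1, 817), "water_fraction")
  expect_error(effectiveAbsorption(1.2, 817), "water_fraction")
  expect_error(effectiveAbsorption(0.5, -1), "mu_a_water")
})

test_that("thin-layer decadic absorbance reproduces the skin-layer bounds", {
  # 10% water / 10 um and 30% water / 20 um bracket the stratum corneum
  expect_equal(layerAbsorbance(81.7, 10), 81.7 * 10e-4 / log(10))
  expect_equal(round(layerAbsorbance(81.7, 10), 2), 0.04)
  expect_equal(round(layerAbsorbance(245.1, 20), 2), 0.21)
  expect_identical(layerAbsorbance(0, 20), 0)
  expect_error(layerAbsorbance(-1, 10), ">= 0")
  expect_error(layerAbsorbance(10, -1), ">= 0")
})

test_that("absorbance is bilinear: halving mu_a and doubling thickness cancel", {
  mu <- c(10, 81.7, 245.1, 817)
  t_um <- c(5, 10, 20, 40)
  expect_equal(layerAbsorbance(mu, t_um), layerAbsorbance(mu / 2, 2 * t_um))
  expect_equal(layerAbsorbance(3 * mu, t_um), 3 * layerAbsorbance(mu, t_um))
})

test_that("penetration depth is the exact reciprocal of the absorption coefficient", {
  expect_equal(penetrationDepth(245.1) * 245.1, 1e4)
  expect_equal(round(penetrationDepth(245.1), 1), 40.8)
  expect_equal(round(penetrationDepth(817), 1), 12.2)
  expect_identical(penetrationDepth(1e4), 1)
  mu <- 10^seq(-2, 4, length.out = 25)
  expect_equal(penetrationDepth(mu) * mu, rep(1e4, length(mu)))
  expect_error(penetrationDepth(0), "> 0")
  expect_error(penetrationDepth(-5), "> 0")
})

test_that("absorbance spectra peak at band centres", {
  grid <- defaultGrid()
  layer <- LayerOptics(1000, water_fraction = 0.8,
                       bands = absorptionBands(c(990, 1110), 8, 30))
  a <- buildAbsorbanceSpectrum(layer, grid)
  expect_s4_class(a, "Spectrum")
  expect_identical(spectrumKind(a), "absorbance_Bel")
  v <- spectrumValues(a)
  # local maxima within one grid step of each band centre
  for (ctr in c(990, 1110)) {
    win <- which(abs(grid - ctr) <= 20)
    expect_lte(abs(grid[win][which.max(v[win])] - ctr), 2)
  }
  expect_error(buildAbsorbanceSpectrum(layer, numeric()), "non-empty")
})

test_that("band-free dry layer gives a zero spectrum; mirrored bands give symmetry", {
  grid <- seq(950, 1150, by = 2)
  empty <- LayerOptics(10, water_fraction = 0)
  expect_equal(spectrumValues(buildAbsorbanceSpectrum(empty, grid)),
               rep(0, length(grid)))
  mid <- mean(range(grid))
  sym <- LayerOptics(10, water_fraction = 0,
                     bands = absorptionBands(c(mid - 40, mid + 40), 6, 15))
  v <- spectrumValues(buildAbsorbanceSpectrum(sym, grid))
  expect_equal(v, rev(v))
})

test_that("absorbance spectra are additive over band lists", {
  grid <- seq(930, 1200, by = 2)
  b1 <- absorptionBands(990, 8, 20)
  b2 <- absorptionBands(c(1030, 1110), 10, 15)
  mk <- function(b) buildAbsorbanceSpectrum(
    LayerOptics(15, water_fraction = 0.2, bands = b), grid)
  baseline <- buildAbsorbanceSpectrum(LayerOptics(15, water_fraction = 0.2), grid)
  expect_equal(spectrumValues(mk(rbind(b1, b2))),
               spectrumValues(mk(b1)) + spectrumValues(mk(b2)) -
                 spectrumValues(baseline))
})

test_that("transmitted fraction follows the decadic Beer-Lambert complement", {
  expect_identical(transmittedFraction(0), 1)
  expect_equal(transmittedFraction(1), 0.1)
  expect_equal(transmittedFraction(0.21), 10^-0.21)
  expect_equal(round(transmittedFraction(0.21), 4), 0.6166)
  expect_error(transmittedFraction(-0.1), ">= 0")
  # transmission through a layer decreases monotonically with thickness
  t_um <- seq(1, 100, by = 1)
  tr <- transmittedFraction(layerAbsorbance(245.1, t_um))
  expect_true(all(diff(tr) < 0))
})
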