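#' Effective absorption coefficient of a wet tissue layer
#'
#' The mid-infrared absorption of skin layers in the 930--1200 cm\eqn{^{-1}}
#' band is dominated by water, so the effective (band-averaged) absorption
#' coefficient of a layer is modelled as the water absorption coefficient
#' scaled by the layer's water content.
#'
#' @param water_fraction water volume fraction, in [0, 1]. Stratum corneum is
#'   typically 0.10--0.30; interstitial-fluid-like media are ~0.8 or more.
#' @param mu_a_water water absorption coefficient in cm^-1 (default 817).
#' @return effective absorption coefficient in cm^-1.
#' @examples
#' effectiveAbsorption(0.3)           # wettest stratum corneum, 245.1 cm^-1
#' effectiveAbsorption(0.1, 817)      # driest, 81.7 cm^-1
#' @export
effectiveAbsorption <- function(water_fraction, mu_a_water = 817) {
  if (any(!is.finite(water_fraction)) || any(water_fraction < 0) ||
      any(water_fraction > 1))
    stop("water_fraction must lie in [0, 1]")
  if (any(!is.finite(mu_a_water)) || any(mu_a_water < 0))
    stop("mu_a_water must be >= 0")
  water_fraction * mu_a_water
}

#' Decadic absorbance of a thin layer
#'
#' Beer--Lambert absorbance in Bel: \eqn{A = \mu_a t / \ln 10} with the
#' absorption coefficient \eqn{\mu_a} in cm^-1 and thickness \eqn{t} converted
#' from micrometres to cm. The division by \eqn{\ln 10} converts the natural-log
#' attenuation exponent to the decadic scale, so that
#' \code{transmittedFraction(A) == 10^-A}.
#'
#' @param mu_a_eff effective absorption coefficient, cm^-1, >= 0.
#' @param thickness_um layer thickness in micrometres, >= 0.
#' @return decadic absorbance in Bel.
#' @examples
#' layerAbsorbance(effectiveAbsorption(0.1), 10)  # ~0.04 Bel
#' layerAbsorbance(effectiveAbsorption(0.3), 20)  # ~0.21 Bel
#' @export
layerAbsorbance <- function(mu_a_eff, thickness_um) {
  if (any(!is.finite(mu_a_eff)) || any(mu_a_eff < 0))
    stop("mu_a_eff must be >= 0")
  if (any(!is.finite(thickness_um)) || any(thickness_um < 0))
    stop("thickness_um must be >= 0")
  mu_a_eff * (thickness_um * 1e-4) / log(10)
}

#' Optical penetration depth
#'
#' Reciprocal of the effective absorption coefficient, expressed in
#' micrometres: \code{1e4 / mu_a_eff}. For the wettest stated stratum corneum
#' (30\% water, 817 cm^-1 water coefficient) this gives ~40 um, the maximum
#' depth from which a photoacoustic signal can be expected.
#'
#' @param mu_a_eff effective absorption coefficient in cm^-1, > 0.
#' @return penetration depth in micrometres.
#' @examples
#' penetrationDepth(effectiveAbsorption(0.3))  # 40.8 um
#' @export
penetrationDepth <- function(mu_a_eff) {
  if (any(!is.finite(mu_a_eff)) || any(mu_a_eff <= 0))
    stop("mu_a_eff must be > 0")
  1e4 / mu_a_eff
}

# mu_a(nu) in cm^-1 on a grid: flat water term plus Gaussian bands
.absorptionCoefficientOnGrid <- function(layer, grid) {
  mu <- rep(effectiveAbsorption(layer@water_fraction, layer@mu_a_water),
            length(grid))
  b <- layer@bands
  if (nrow(b) > 0L)
    for (i in seq_len(nrow(b)))
      mu <- mu + b$amplitude[i] * exp(-(grid - b$center[i])^2 / (2 * b$width[i]^2))
  mu
}

#' Absorbance spectrum of an optical layer
#'
#' Evaluates the layer's absorption coefficient
#' \eqn{\mu_a(\nu) = w\,\mu_{a,\mathrm{water}} + \sum_k a_k
#' \exp\{-(\nu - c_k)^2 / 2\sigma_k^2\}} on the grid and converts it to decadic
#' absorbance via [layerAbsorbance()]. Band centres appear as local maxima of
#' the returned spectrum when bands are separated by more than ~3 sigma.
#'
#' @param layer a [LayerOptics-class] object.
#' @param grid ascending wavenumber grid in cm^-1 (default 930--1200 cm^-1
#'   every 2 cm^-1, the instrument's tuning range).
#' @return a [Spectrum-class] with kind \code{"absorbance_Bel"}.
#' @examples
#' sc <- LayerOptics(15, water_fraction = 0.2,
#'                   bands = absorptionBands(c(1030, 1080), 10, 120))
#' a <- buildAbsorbanceSpectrum(sc)
#' wavenumbers(a)[which.max(spectrumValues(a))]
#' @export
buildAbsorbanceSpectrum <- function(layer, grid = defaultGrid()) {
  stopifnot(is(layer, "LayerOptics"))
  if (length(grid) == 0L) stop("wavenumber grid must be non-empty")
  mu <- .absorptionCoefficientOnGrid(layer, grid)
  Spectrum(grid, layerAbsorbance(mu, layer@thickness_um), "absorbance_Bel")
}

#' Fraction of light transmitted through an absorbing layer
#'
#' Decadic Beer--Lambert complement, \code{10^-A}.
#'
#' @param absorbance decadic absorbance in Bel, >= 0.
#' @return transmitted fraction in (0, 1].
#' @examples
#' transmittedFraction(0.21)  # 0.617
#' @export
transmittedFraction <- function(absorbance) {
  if (any(!is.finite(absorbance)) || any(absorbance < 0))
    stop("absorbance must be >= 0")
  10^(-absorbance)
}

#' Default instrument wavenumber grid
#'
#' The laser tunes over 930--1200 cm^-1; spectra are represented on this range
#' at 2 cm^-1 spacing by default.
#'
#' @param lo,hi grid limits in cm^-1.
#' @param step grid spacing in cm^-1.
#' @return ascending numeric grid.
#' @export
defaultGrid <- function(lo = 930, hi = 1200, step = 2) seq(lo, hi, by = step)
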