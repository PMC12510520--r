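#' Photoacoustic amplitude in the optically thick regime
#'
#' For absorbers thicker than a few tens of micrometres, stronger absorption
#' confines the deposited heat to a thinner surface layer, so the heated
#' volume -- and with it the thermoelastic signal amplitude -- scales as the
#' reciprocal of the absorption coefficient: \eqn{S = c / \mu_a}. Absorption
#' peaks therefore appear as dips in the photoacoustic spectrum.
#'
#' @param mu_a absorption coefficient in cm^-1, > 0.
#' @param scale proportionality constant c, a.u.
#' @return signal amplitude, a.u.
#' @export
pasAmplitudeThick <- function(mu_a, scale = 1) {
  if (any(!is.finite(mu_a)) || any(mu_a <= 0))
    stop("mu_a must be > 0 in the optically thick regime")
  scale / mu_a
}

#' Synthesize a photoacoustic spectrum of a layered sample
#'
#' The bulk absorber responds in the optically thick regime
#' ([pasAmplitudeThick()]); an optional thin top layer attenuates the incident
#' light once (one-way; the returning wave is acoustic, not optical):
#' \deqn{S(\nu) = c \; 10^{-A_{top}(\nu)} \; / \; \mu_{a,bulk}(\nu).}
#' Band centres of the bulk absorber (e.g. glucose at 990 and 1110 cm^-1) and
#' of the top layer (e.g. collagen protein bands at 1030 and 1080 cm^-1)
#' both appear as local minima of the synthesized spectrum.
#'
#' @param sample a [LayeredSample-class].
#' @param grid ascending wavenumber grid in cm^-1.
#' @return a [Spectrum-class] with kind \code{"pas_signal_au"}.
#' @examples
#' bulk <- LayerOptics(1000, water_fraction = 0.8,
#'                     bands = absorptionBands(c(990, 1110), 8, 40))
#' s <- synthesizePASSpectrum(LayeredSample(bulk))
#' wavenumbers(s)[which.min(spectrumValues(s))]
#' @export
synthesizePASSpectrum <- function(sample, grid = defaultGrid()) {
  stopifnot(is(sample, "LayeredSample"))
  if (length(grid) == 0L) stop("wavenumber grid must be non-empty")
  mu_bulk <- .absorptionCoefficientOnGrid(sample@bulk, grid)
  if (any(mu_bulk <= 0))
    stop("bulk absorption coefficient must be > 0 everywhere; ",
         "add a small water floor to the bulk layer")
  trans <- if (is.null(sample@top_layer)) 1 else
    transmittedFraction(spectrumValues(
      buildAbsorbanceSpectrum(sample@top_layer, grid)))
  Spectrum(grid, sample@signal_scale * trans / mu_bulk, "pas_signal_au")
}

#' Average irradiance of the laser spot
#'
#' Average power density over the 1/e^2 spot area:
#' \eqn{E = P / (\pi (d/2)^2)}. 12 mW over a 1-mm spot gives 1.5 W/cm^2, the
#' irradiance at which skin exposure stayed within safety guidelines.
#'
#' @param power_mW optical power in milliwatts, > 0.
#' @param spot_diameter_mm 1/e^2 spot diameter in millimetres, > 0.
#' @return irradiance in W/cm^2.
#' @examples
#' averageIrradiance(12, 1)  # 1.53 W/cm^2
#' @export
averageIrradiance <- function(power_mW, spot_diameter_mm) {
  if (any(!is.finite(c(power_mW, spot_diameter_mm))) ||
      any(c(power_mW, spot_diameter_mm) <= 0))
    stop("power and spot diameter must be > 0")
  (power_mW * 1e-3) / (pi * (spot_diameter_mm / 2 * 0.1)^2)
}
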