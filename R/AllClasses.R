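#' @import methods
#' @importFrom stats rnorm sd predict lm coef setNames
#' @importFrom utils read.csv write.csv
NULL

.SPECTRUM_KINDS <- c("absorbance_Bel", "pas_signal_au", "laser_power_au")

#' Single-channel spectrum on a wavenumber grid
#'
#' A \code{Spectrum} holds values on a strictly ascending wavenumber grid
#' (cm\eqn{^{-1}}) together with a \code{kind} tag identifying the physical
#' quantity: decadic absorbance (\code{"absorbance_Bel"}), a photoacoustic
#' signal (\code{"pas_signal_au"}) or a laser power reference
#' (\code{"laser_power_au"}).
#'
#' @slot wavenumbers numeric, strictly ascending grid in cm^-1.
#' @slot values numeric, same length as \code{wavenumbers}, finite.
#' @slot kind character scalar, one of \code{"absorbance_Bel"},
#'   \code{"pas_signal_au"}, \code{"laser_power_au"}.
#'
#' @seealso [Spectrum()] for the user-facing constructor.
#' @export
setClass("Spectrum",
  representation(wavenumbers = "numeric", values = "numeric", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@wavenumbers) != length(object@values))
      msg <- c(msg, "wavenumbers and values must have equal length")
    if (length(object@wavenumbers) == 0L)
      msg <- c(msg, "spectrum must contain at least one point")
    if (any(!is.finite(object@wavenumbers)) || any(!is.finite(object@values)))
      msg <- c(msg, "wavenumbers and values must be finite")
    if (length(object@wavenumbers) > 1L && any(diff(object@wavenumbers) <= 0))
      msg <- c(msg, "wavenumber grid must be strictly ascending")
    if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS)
      msg <- c(msg, sprintf("kind must be one of: %s",
                            paste(.SPECTRUM_KINDS, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Construct a Spectrum
#'
#' @param wavenumbers strictly ascending numeric grid (cm^-1).
#' @param values numeric values, one per grid point.
#' @param kind one of \code{"absorbance_Bel"}, \code{"pas_signal_au"},
#'   \code{"laser_power_au"}.
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(seq(930, 1200, by = 2), rep(1, 136), "pas_signal_au")
#' length(wavenumbers(s))
#' @export
Spectrum <- function(wavenumbers, values, kind = "pas_signal_au") {
  new("Spectrum", wavenumbers = as.numeric(wavenumbers),
      values = as.numeric(values), kind = kind)
}

#' Optical description of one tissue layer
#'
#' Thickness, water fraction and a table of Gaussian absorption bands. The
#' effective absorption coefficient at wavenumber nu is
#' \code{water_fraction * mu_a_water} plus the sum of Gaussian band
#' contributions \code{amplitude * exp(-(nu - center)^2 / (2 width^2))}.
#'
#' @slot thickness_um layer thickness in micrometres, > 0.
#' @slot water_fraction volume fraction of water in [0, 1].
#' @slot mu_a_water water absorption coefficient in cm^-1 (default 817,
#'   the mid-infrared value used for skin-layer absorbance estimates).
#' @slot bands data.frame with columns \code{center}, \code{width},
#'   \code{amplitude} (cm^-1); may have zero rows.
#' @export
setClass("LayerOptics",
  representation(thickness_um = "numeric", water_fraction = "numeric",
                 mu_a_water = "numeric", bands = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@thickness_um) != 1L || !is.finite(object@thickness_um) ||
        object@thickness_um <= 0)
      msg <- c(msg, "thickness_um must be a single positive number")
    if (length(object@water_fraction) != 1L || is.na(object@water_fraction) ||
        object@water_fraction < 0 || object@water_fraction > 1)
      msg <- c(msg, "water_fraction must lie in [0, 1]")
    if (length(object@mu_a_water) != 1L || is.na(object@mu_a_water) ||
        object@mu_a_water < 0)
      msg <- c(msg, "mu_a_water must be >= 0")
    b <- object@bands
    if (!all(c("center", "width", "amplitude") %in% names(b)))
      msg <- c(msg, "bands must have columns center, width, amplitude")
    else if (nrow(b) > 0L) {
      if (any(b$width <= 0)) msg <- c(msg, "band widths must be > 0")
      if (any(b$amplitude < 0)) msg <- c(msg, "band amplitudes must be >= 0")
    }
    if (length(msg)) msg else TRUE
  })

#' Build a table of Gaussian absorption bands
#'
#' @param center band centres in cm^-1.
#' @param width Gaussian sigma in cm^-1, > 0 (recycled).
#' @param amplitude peak contribution to the absorption coefficient in cm^-1,
#'   >= 0 (recycled).
#' @return data.frame with columns \code{center}, \code{width},
#'   \code{amplitude}.
#' @examples
#' absorptionBands(c(990, 1110), width = 8, amplitude = 25)
#' @export
absorptionBands <- function(center = numeric(), width = numeric(),
                            amplitude = numeric()) {
  if (length(center) == 0L)
    return(data.frame(center = numeric(), width = numeric(),
                      amplitude = numeric()))
  data.frame(center = as.numeric(center),
             width = rep_len(as.numeric(width), length(center)),
             amplitude = rep_len(as.numeric(amplitude), length(center)))
}

#' Construct a LayerOptics object
#'
#' @param thickness_um thickness in micrometres.
#' @param water_fraction water volume fraction in [0, 1].
#' @param bands band table from [absorptionBands()].
#' @param mu_a_water water absorption coefficient (cm^-1).
#' @return A [LayerOptics-class] object.
#' @examples
#' isf <- LayerOptics(1000, water_fraction = 0.8,
#'                    bands = absorptionBands(c(990, 1110), 8, 25))
#' @export
LayerOptics <- function(thickness_um, water_fraction = 0,
                        bands = absorptionBands(), mu_a_water = 817) {
  new("LayerOptics", thickness_um = as.numeric(thickness_um),
      water_fraction = as.numeric(water_fraction),
      mu_a_water = as.numeric(mu_a_water), bands = bands)
}

#' Acoustic description of one layer
#'
#' @slot thickness_mm thickness in millimetres, > 0.
#' @slot sound_speed sound speed in m/s, > 0.
#' @slot impedance acoustic impedance in MRayl, > 0.
#' @export
setClass("AcousticLayer",
  representation(thickness_mm = "numeric", sound_speed = "numeric",
                 impedance = "numeric"),
  validity = function(object) {
    vals <- c(object@thickness_mm, object@sound_speed, object@impedance)
    if (length(vals) != 3L || any(!is.finite(vals)) || any(vals <= 0))
      "thickness_mm, sound_speed and impedance must all be single positive numbers"
    else TRUE
  })

#' Construct an AcousticLayer
#'
#' @param thickness_mm thickness in mm.
#' @param sound_speed sound speed in m/s.
#' @param impedance acoustic impedance in MRayl.
#' @return An [AcousticLayer-class] object.
#' @examples
#' gel <- AcousticLayer(2, sound_speed = 1389, impedance = 1.6)
#' @export
AcousticLayer <- function(thickness_mm, sound_speed, impedance = 1.6) {
  new("AcousticLayer", thickness_mm = as.numeric(thickness_mm),
      sound_speed = as.numeric(sound_speed), impedance = as.numeric(impedance))
}

#' Amplitude versus acoustic modulation frequency
#'
#' @slot frequencies Hz, strictly ascending.
#' @slot amplitudes arbitrary units, >= 0, same length.
#' @export
setClass("FrequencySweep",
  representation(frequencies = "numeric", amplitudes = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@frequencies) != length(object@amplitudes))
      msg <- c(msg, "frequencies and amplitudes must have equal length")
    if (length(object@frequencies) > 1L && any(diff(object@frequencies) <= 0))
      msg <- c(msg, "frequencies must be strictly ascending")
    if (any(!is.finite(object@amplitudes)) || any(object@amplitudes < 0))
      msg <- c(msg, "amplitudes must be finite and >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a FrequencySweep
#' @param frequencies Hz, ascending.
#' @param amplitudes a.u., >= 0.
#' @return A [FrequencySweep-class] object.
#' @export
FrequencySweep <- function(frequencies, amplitudes) {
  new("FrequencySweep", frequencies = as.numeric(frequencies),
      amplitudes = as.numeric(amplitudes))
}

#' Two-layer optical + acoustic sample for photoacoustic synthesis
#'
#' A bulk absorber (interstitial-fluid-like, optically thick) optionally
#' covered by a thin top layer (stratum-corneum-like) that attenuates the
#' incident light, together with the acoustic layer properties used by the
#' resonance model.
#'
#' @slot top_layer [LayerOptics-class] or NULL; thin attenuating cover.
#' @slot bulk [LayerOptics-class]; the optically thick absorber probed by the
#'   photoacoustic signal.
#' @slot acoustic [AcousticLayer-class].
#' @slot signal_scale positive scale factor (a.u.).
#' @export
setClass("LayeredSample",
  representation(top_layer = "ANY", bulk = "LayerOptics",
                 acoustic = "AcousticLayer", signal_scale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.null(object@top_layer) && !is(object@top_layer, "LayerOptics"))
      msg <- c(msg, "top_layer must be NULL or a LayerOptics object")
    if (length(object@signal_scale) != 1L || !is.finite(object@signal_scale) ||
        object@signal_scale <= 0)
      msg <- c(msg, "signal_scale must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Construct a LayeredSample
#'
#' @param bulk [LayerOptics-class] for the optically thick bulk absorber.
#' @param top_layer optional [LayerOptics-class] cover layer (or NULL).
#' @param acoustic [AcousticLayer-class]; defaults to a 2-mm layer with the
#'   epidermal sound speed 1580 m/s.
#' @param signal_scale overall signal scale (a.u.).
#' @return A [LayeredSample-class] object.
#' @export
LayeredSample <- function(bulk, top_layer = NULL,
                          acoustic = AcousticLayer(2, 1580, 1.6),
                          signal_scale = 1000) {
  new("LayeredSample", top_layer = top_layer, bulk = bulk,
      acoustic = acoustic, signal_scale = as.numeric(signal_scale))
}

#' Fitted PLS-DA model
#'
#' Weights, loadings and the assembled regression vector of a univariate-
#' response NIPALS partial least squares fit on column-centred data, plus the
#' 0/1 decision threshold applied to the clipped prediction (the class
#' posterior).
#'
#' @slot x_mean per-feature training column means.
#' @slot y_mean training response mean.
#' @slot weights p x A weight matrix W.
#' @slot loadings p x A X-loading matrix P.
#' @slot y_loadings length-A response loadings q.
#' @slot regression_vector length-p vector b with yhat = (x - x_mean) b + y_mean.
#' @slot n_latent number of latent variables retained.
#' @slot decision_threshold posterior threshold for class 1 (default 0.5).
#' @export
setClass("PLSDAModel",
  representation(x_mean = "numeric", y_mean = "numeric", weights = "matrix",
                 loadings = "matrix", y_loadings = "numeric",
                 regression_vector = "numeric", n_latent = "integer",
                 decision_threshold = "numeric"),
  validity = function(object) {
    msg <- character()
    p <- length(object@x_mean)
    A <- object@n_latent
    if (A < 1L) msg <- c(msg, "n_latent must be >= 1")
    if (nrow(object@weights) != p || nrow(object@loadings) != p)
      msg <- c(msg, "weights and loadings must have one row per feature")
    if (ncol(object@weights) != A || ncol(object@loadings) != A ||
        length(object@y_loadings) != A)
      msg <- c(msg, "weights, loadings and y_loadings must have n_latent columns")
    if (length(object@regression_vector) != p)
      msg <- c(msg, "regression_vector must have one entry per feature")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Spectrum", function(object) {
  wn <- object@wavenumbers
  cat(sprintf("Spectrum [%s]: %d points, %.0f-%.0f cm-1\n",
              object@kind, length(wn), min(wn), max(wn)))
  cat(sprintf("  values: min %.4g, max %.4g\n",
              min(object@values), max(object@values)))
})

setMethod("show", "LayerOptics", function(object) {
  cat(sprintf("LayerOptics: %.3g um thick, water fraction %.2f, %d band(s)\n",
              object@thickness_um, object@water_fraction, nrow(object@bands)))
})

setMethod("show", "AcousticLayer", function(object) {
  cat(sprintf("AcousticLayer: %.3g mm, v = %.0f m/s, Z = %.2f MRayl\n",
              object@thickness_mm, object@sound_speed, object@impedance))
})

setMethod("show", "FrequencySweep", function(object) {
  f <- object@frequencies
  cat(sprintf("FrequencySweep: %d points, %.1f-%.1f kHz\n",
              length(f), min(f) / 1e3, max(f) / 1e3))
})

setMethod("show", "LayeredSample", function(object) {
  cat("LayeredSample\n")
  cat("  top layer: ", if (is.null(object@top_layer)) "none" else
    sprintf("%.3g um, %d band(s)", object@top_layer@thickness_um,
            nrow(object@top_layer@bands)), "\n", sep = "")
  cat(sprintf("  bulk: water fraction %.2f, %d band(s)\n",
              object@bulk@water_fraction, nrow(object@bulk@bands)))
  cat(sprintf("  signal scale: %.3g a.u.\n", object@signal_scale))
})

setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf("PLSDAModel: %d latent variable(s), %d features, threshold %.2f\n",
              object@n_latent, length(object@x_mean), object@decision_threshold))
})
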