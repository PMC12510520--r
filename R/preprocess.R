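#' Preprocessing configuration
#'
#' The spectral preprocessing chain is fixed in order: laser-power
#' normalisation, min-max scaling to [0, 1] over \code{[scale_lo, scale_hi]}
#' (970--1162 cm^-1), then restriction of the model features to the target
#' window \code{[band_lo, band_hi]} (1022--1148 cm^-1). All window endpoints
#' are inclusive. The band window must lie inside the scaling window, which
#' guarantees the selected features lie in [0, 1].
#'
#' @param scale_lo,scale_hi min-max scaling window, cm^-1.
#' @param band_lo,band_hi feature (target) window, cm^-1.
#' @param smoothing_window trailing moving-average window for the glucose
#'   reference time series.
#' @return a named list of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(scale_lo = 970, scale_hi = 1162,
                             band_lo = 1022, band_hi = 1148,
                             smoothing_window = 3L) {
  if (scale_lo >= scale_hi) stop("scale_lo must be < scale_hi")
  if (band_lo > band_hi) stop("band_lo must be <= band_hi")
  if (band_lo < scale_lo || band_hi > scale_hi)
    stop("band window must lie inside the scaling window")
  structure(list(scale_lo = scale_lo, scale_hi = scale_hi, band_lo = band_lo,
                 band_hi = band_hi,
                 smoothing_window = as.integer(smoothing_window)),
            class = "PreprocessConfig")
}

#' Normalize a photoacoustic spectrum by the laser power
#'
#' Pointwise quotient of the raw signal by a laser-power reference spectrum on
#' the identical grid; removes the source's wavenumber-dependent power
#' profile.
#'
#' @param raw a [Spectrum-class] of kind \code{"pas_signal_au"}.
#' @param power a [Spectrum-class] of kind \code{"laser_power_au"} on the same
#'   grid, with strictly positive values.
#' @return a [Spectrum-class] of kind \code{"pas_signal_au"}.
#' @export
normalizeByPower <- function(raw, power) {
  stopifnot(is(raw, "Spectrum"), is(power, "Spectrum"))
  if (length(wavenumbers(raw)) != length(wavenumbers(power)) ||
      any(wavenumbers(raw) != wavenumbers(power)))
    stop("raw and power spectra must share the same wavenumber grid")
  if (any(spectrumValues(power) <= 0))
    stop("laser power must be > 0 at every grid point")
  Spectrum(wavenumbers(raw), spectrumValues(raw) / spectrumValues(power),
           "pas_signal_au")
}

.minmaxVector <- function(wn, v, lo, hi) {
  in_win <- wn >= lo & wn <= hi
  if (!any(in_win)) stop("scaling window does not overlap the grid")
  mn <- min(v[in_win]); mx <- max(v[in_win])
  if (mx == mn)
    stop("spectrum is constant on the scaling window; cannot min-max scale")
  (v - mn) / (mx - mn)
}

#' Min-max scale a spectrum over a wavenumber window
#'
#' Extrema are computed only on grid points inside the closed window
#' \code{[lo, hi]}; the affine rescaling is then applied to every point, so
#' values inside the window land in [0, 1] with both endpoints attained.
#' Scale- and offset-invariant: affine transforms of the input give identical
#' output.
#'
#' @param spectrum a [Spectrum-class].
#' @param lo,hi closed scaling window in cm^-1.
#' @return a rescaled [Spectrum-class] of the same kind.
#' @export
minMaxScale <- function(spectrum, lo = 970, hi = 1162) {
  stopifnot(is(spectrum, "Spectrum"))
  Spectrum(wavenumbers(spectrum),
           .minmaxVector(wavenumbers(spectrum), spectrumValues(spectrum), lo, hi),
           spectrumKind(spectrum))
}

#' Extract the model feature vector from a spectrum
#'
#' Values at grid points inside the closed window \code{[lo, hi]}, ascending,
#' named \code{wn_<wavenumber>}. On the default 2 cm^-1 grid the
#' 1022--1148 cm^-1 target window yields 64 features.
#'
#' @param spectrum a [Spectrum-class].
#' @param lo,hi closed feature window in cm^-1.
#' @return named numeric vector of features.
#' @export
selectBand <- function(spectrum, lo = 1022, hi = 1148) {
  stopifnot(is(spectrum, "Spectrum"))
  wn <- wavenumbers(spectrum)
  in_win <- wn >= lo & wn <= hi
  if (!any(in_win)) stop("feature window does not overlap the grid")
  setNames(spectrumValues(spectrum)[in_win], paste0("wn_", wn[in_win]))
}

#' Preprocess a dataset into a feature matrix
#'
#' Applies the fixed chain (min-max scaling over the scaling window, then
#' band selection) to every spectrum of a [PASDataset-class]. Spectra from the
#' generator are already power-normalised; apply [normalizeByPower()] first
#' when working from raw instrument signals.
#'
#' @param dataset a [PASDataset-class].
#' @param config a [preprocessConfig()] list.
#' @return list with \code{X} (records x features matrix), \code{y} (integer
#'   0/1 labels), \code{glucose} (smoothed reference, mg/dL) and
#'   \code{wavenumbers} (feature wavenumbers, cm^-1).
#' @examples
#' ds <- generateDataset(10, noise = noiseParams("fixed", seed = 7))
#' dim(preprocessDataset(ds)$X)
#' @export
preprocessDataset <- function(dataset, config = preprocessConfig()) {
  stopifnot(is(dataset, "PASDataset"), inherits(config, "PreprocessConfig"))
  wn <- wavenumbers(dataset)
  m <- spectraMatrix(dataset)
  scaled <- apply(m, 2, .minmaxVector, wn = wn,
                  lo = config$scale_lo, hi = config$scale_hi)
  in_band <- wn >= config$band_lo & wn <= config$band_hi
  if (!any(in_band)) stop("feature window does not overlap the grid")
  X <- t(scaled[in_band, , drop = FALSE])
  colnames(X) <- paste0("wn_", wn[in_band])
  list(X = X, y = classLabels(dataset), glucose = glucoseSmoothed(dataset),
       wavenumbers = wn[in_band])
}
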