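#' Acoustic wavelength from sound speed and frequency
#'
#' \eqn{\lambda = v / f}.
#'
#' @param sound_speed m/s, > 0.
#' @param frequency Hz, > 0.
#' @return wavelength in metres.
#' @examples
#' acousticWavelength(1389, 520875)  # 2.667 mm at the m = 1 gel resonance
#' @export
acousticWavelength <- function(sound_speed, frequency) {
  if (any(!is.finite(sound_speed)) || any(sound_speed <= 0))
    stop("sound_speed must be > 0")
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be > 0")
  sound_speed / frequency
}

#' Quarter-wave resonance frequencies of a layer
#'
#' Standing waves form in a layer of thickness \eqn{t} when
#' \eqn{t = (2m+1)\lambda/4}, i.e. at the odd-harmonic family
#' \eqn{f_m = (2m+1)\,v / (4t)}, m = 0, 1, 2, ... Driving the laser modulation
#' at one of these frequencies enhances the photoacoustic signal.
#'
#' @param layer an [AcousticLayer-class].
#' @param max_mode largest mode index m to return (>= 0).
#' @return data.frame with columns \code{mode} and \code{frequency_hz},
#'   strictly increasing in \code{mode}.
#' @examples
#' gel <- AcousticLayer(2, 1389)
#' resonanceFrequencies(gel, 1)   # m = 1: 520.9 kHz
#' @export
resonanceFrequencies <- function(layer, max_mode = 3) {
  stopifnot(is(layer, "AcousticLayer"))
  if (length(max_mode) != 1L || is.na(max_mode) || max_mode < 0)
    stop("max_mode must be >= 0")
  m <- 0:max_mode
  t_m <- layer@thickness_mm * 1e-3
  data.frame(mode = m, frequency_hz = (2 * m + 1) * layer@sound_speed / (4 * t_m))
}

#' Pressure reflection coefficient at an acoustic interface
#'
#' \eqn{r = (Z_2 - Z_1)/(Z_2 + Z_1)} for a wave travelling from medium 1
#' (impedance \code{z_incident}) into medium 2 (\code{z_transmitted}). Used as
#' a scalar upper-bound diagnostic of interface reflection in layered
#' phantoms, e.g. dried collagen (4.6 MRayl) onto polyethylene (1.9 MRayl).
#'
#' @param z_incident,z_transmitted acoustic impedances in MRayl, > 0.
#' @return reflection coefficient in (-1, 1).
#' @examples
#' reflectionCoefficient(4.6, 1.9)  # -0.415, dried collagen -> PE
#' @export
reflectionCoefficient <- function(z_incident, z_transmitted) {
  if (any(!is.finite(c(z_incident, z_transmitted))) ||
      any(c(z_incident, z_transmitted) <= 0))
    stop("impedances must be > 0")
  (z_transmitted - z_incident) / (z_transmitted + z_incident)
}

#' Simulated frequency response of the photoacoustic signal
#'
#' Damped-resonator response: each quarter-wave mode contributes a Lorentzian
#' \eqn{L_m(f) = 1 / (1 + (2Q(f - f_m)/f_m)^2)} and the amplitude is
#' \code{baseline * (1 + gain * sum_m L_m(f))}. With the default
#' \code{resonance_gain = 3} the on-resonance amplitude is four times the
#' off-resonance baseline, the enhancement observed for a 2-mm gel; the gain
#' is transducer- and coupling-specific and fully configurable.
#'
#' @param layer an [AcousticLayer-class].
#' @param frequencies ascending modulation frequencies in Hz.
#' @param quality_factor shared resonator Q, > 0.
#' @param baseline off-resonance amplitude, a.u. > 0.
#' @param resonance_gain peak amplitude gain relative to baseline, >= 0.
#' @param max_mode highest thickness mode included.
#' @param extra_modes optional numeric vector of additional resonance
#'   frequencies (Hz), e.g. lateral modes, given the same Q and gain.
#' @return a [FrequencySweep-class].
#' @examples
#' gel <- AcousticLayer(2, 1389)
#' sw <- frequencyResponse(gel, seq(4e5, 7e5, by = 500))
#' findResonancePeaks(sw)
#' @export
frequencyResponse <- function(layer, frequencies, quality_factor = 40,
                              baseline = 1, resonance_gain = 3,
                              max_mode = 5, extra_modes = NULL) {
  stopifnot(is(layer, "AcousticLayer"))
  if (length(frequencies) == 0L) stop("frequency list must be non-empty")
  if (quality_factor <= 0 || baseline <= 0 || resonance_gain < 0)
    stop("quality_factor and baseline must be > 0; resonance_gain >= 0")
  fm <- c(resonanceFrequencies(layer, max_mode)$frequency_hz, extra_modes)
  amp <- rep(0, length(frequencies))
  for (f0 in fm)
    amp <- amp + 1 / (1 + (2 * quality_factor * (frequencies - f0) / f0)^2)
  FrequencySweep(frequencies, baseline * (1 + resonance_gain * amp))
}

#' Locate resonance peaks in a frequency sweep
#'
#' Returns local maxima whose topographic prominence exceeds
#' \code{prominence_fraction} of the sweep's amplitude range, in ascending
#' frequency order. Prominence of a peak is its height above the higher of the
#' two deepest valleys separating it from larger peaks (or from the sweep
#' edge). A flat sweep yields an empty result, not an error.
#'
#' @param sweep a [FrequencySweep-class].
#' @param prominence_fraction fraction of the amplitude range in (0, 1).
#' @return numeric vector of peak frequencies in Hz (possibly empty).
#' @export
findResonancePeaks <- function(sweep, prominence_fraction = 0.1) {
  stopifnot(is(sweep, "FrequencySweep"))
  if (prominence_fraction <= 0 || prominence_fraction >= 1)
    stop("prominence_fraction must lie in (0, 1)")
  a <- sweep@amplitudes
  n <- length(a)
  rng <- diff(range(a))
  if (n < 3L || rng == 0) return(numeric())
  is_peak <- which(a[2:(n - 1L)] > a[1:(n - 2L)] &
                   a[2:(n - 1L)] >= a[3:n]) + 1L
  keep <- vapply(is_peak, function(i) {
    h <- a[i]
    # walk left/right to the first sample at least as high; the valley floor
    # on each side bounds the peak's prominence
    left <- a[seq_len(i - 1L)]
    higher_l <- which(left >= h)
    lo_l <- if (length(higher_l)) min(a[(max(higher_l) + 1L):(i - 1L)]) else min(left)
    right <- a[(i + 1L):n]
    higher_r <- which(right >= h)
    lo_r <- if (length(higher_r))
      min(a[(i + 1L):(i + min(higher_r) - 1L)]) else min(right)
    (h - max(lo_l, lo_r)) > prominence_fraction * rng
  }, logical(1))
  sweep@frequencies[is_peak[keep]]
}

#' Layer thickness from an observed resonance frequency
#'
#' Inverse of the quarter-wave condition: \eqn{t = (2m+1)\,v / (4f)}.
#'
#' @param peak_frequency Hz, > 0.
#' @param sound_speed m/s, > 0.
#' @param mode_index assumed mode m, >= 0.
#' @return thickness in millimetres.
#' @examples
#' estimateThickness(503000, 1580, 1)  # interdigital membrane, ~2.4 mm
#' @export
estimateThickness <- function(peak_frequency, sound_speed, mode_index = 0) {
  if (any(!is.finite(peak_frequency)) || any(peak_frequency <= 0))
    stop("peak_frequency must be > 0")
  if (any(!is.finite(sound_speed)) || any(sound_speed <= 0))
    stop("sound_speed must be > 0")
  if (any(mode_index < 0)) stop("mode_index must be >= 0")
  (2 * mode_index + 1) * sound_speed / (4 * peak_frequency) * 1e3
}
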