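#' Parameters of a simulated oral glucose tolerance test
#'
#' Defaults describe a healthy adult drinking a 55-g sugar load after an
#' overnight fast: fasting baseline 90 mg/dL, a 70 mg/dL excursion peaking
#' 45 min after ingestion, sampled every 5 min over the 2 h before and after
#' ingestion.
#'
#' @param baseline_glucose fasting glucose, mg/dL.
#' @param peak_excess excursion height above baseline, mg/dL.
#' @param time_to_peak minutes from ingestion to the excursion maximum.
#' @param decay_time tail decay time constant, minutes.
#' @param sampling_interval minutes between measurements.
#' @param duration_before,duration_after observation window around ingestion,
#'   minutes.
#' @param glucose_noise_sd sd of the fingerstick measurement noise, mg/dL.
#' @return a named list of class \code{"OGTTParams"}.
#' @export
ogttParams <- function(baseline_glucose = 90, peak_excess = 70,
                       time_to_peak = 45, decay_time = 40,
                       sampling_interval = 5, duration_before = 120,
                       duration_after = 120, glucose_noise_sd = 2) {
  p <- list(baseline_glucose = baseline_glucose, peak_excess = peak_excess,
            time_to_peak = time_to_peak, decay_time = decay_time,
            sampling_interval = sampling_interval,
            duration_before = duration_before,
            duration_after = duration_after,
            glucose_noise_sd = glucose_noise_sd)
  if (any(!vapply(p[1:7], function(v) is.finite(v) && v > 0, logical(1))))
    stop("all OGTT durations and amplitudes must be positive")
  if (glucose_noise_sd < 0) stop("glucose_noise_sd must be >= 0")
  structure(p, class = "OGTTParams")
}

#' Acquisition-noise parameters for the dataset generator
#'
#' Repositioning the probe between measurements perturbs the illuminated spot
#' and the acoustic coupling; tissue inhomogeneity then changes the observed
#' band structure, not just the overall gain. This is captured by larger
#' multiplicative jitter defaults in \code{"repositioned"} mode (gain 5\%,
#' band amplitudes 10\%) than in \code{"fixed"} mode (1\%, 2\%). Additive
#' detector noise and a per-day baseline drift are mode-independent; a
#' subject-specific band-position shift (off by default) emulates
#' intersubject variability.
#'
#' @param mode \code{"fixed"} or \code{"repositioned"}.
#' @param additive_sd sd of white additive noise per spectral point, a.u.
#' @param gain_jitter_sd sd of the per-record multiplicative gain jitter.
#' @param band_amplitude_jitter_sd sd of the per-record, per-band relative
#'   amplitude jitter.
#' @param baseline_drift_sd sd of the per-day additive offset, a.u.
#' @param subject_band_shift_sd sd of a common band-centre shift, cm^-1.
#' @param seed integer RNG seed; mandatory for reproducibility.
#' @return a named list of class \code{"NoiseParams"}.
#' @export
noiseParams <- function(mode = c("fixed", "repositioned"),
                        additive_sd = 0.002,
                        gain_jitter_sd = if (mode == "fixed") 0.01 else 0.05,
                        band_amplitude_jitter_sd = if (mode == "fixed") 0.02 else 0.10,
                        baseline_drift_sd = additive_sd,
                        subject_band_shift_sd = 0,
                        seed = 1L) {
  mode <- match.arg(mode)
  p <- list(mode = mode, additive_sd = additive_sd,
            gain_jitter_sd = gain_jitter_sd,
            band_amplitude_jitter_sd = band_amplitude_jitter_sd,
            baseline_drift_sd = baseline_drift_sd,
            subject_band_shift_sd = subject_band_shift_sd,
            seed = as.integer(seed))
  sds <- unlist(p[c(2:6)])
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all noise standard deviations must be >= 0")
  structure(p, class = "NoiseParams")
}

#' Simulated OGTT glucose time course
#'
#' Baseline before ingestion; afterwards a gamma-like excursion
#' \deqn{g(t) = g_0 + \Delta g \,(t/t_p)^k \exp\{k(1 - t/t_p)\}, \quad
#'       k = t_p / \tau,}
#' which peaks exactly at \eqn{t = t_p} and decays with time constant
#' \eqn{\tau} (\code{decay_time}); for \eqn{\tau = t_p} it reduces to the
#' plain \eqn{(t/t_p)\exp(1 - t/t_p)} shape. Gaussian measurement noise of sd
#' \code{glucose_noise_sd} is added, reproducibly from \code{seed}.
#'
#' @param params an [ogttParams()] list.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{time_min} and \code{glucose_mg_dl}.
#' @examples
#' head(ogttGlucoseCurve(ogttParams(glucose_noise_sd = 0), seed = 1))
#' @export
ogttGlucoseCurve <- function(params = ogttParams(), seed = 1L) {
  stopifnot(inherits(params, "OGTTParams"))
  times <- seq(-params$duration_before, params$duration_after,
               by = params$sampling_interval)
  g <- rep(params$baseline_glucose, length(times))
  post <- times > 0
  k <- params$time_to_peak / params$decay_time
  tt <- times[post] / params$time_to_peak
  g[post] <- g[post] + params$peak_excess * tt^k * exp(k * (1 - tt))
  if (params$glucose_noise_sd > 0) {
    set.seed(as.integer(seed))
    g <- g + rnorm(length(g), 0, params$glucose_noise_sd)
  }
  data.frame(time_min = times, glucose_mg_dl = g)
}

#' Trailing moving average
#'
#' \code{out[i]} is the mean of \code{x[i]} and the \code{window - 1}
#' immediately preceding values; leading windows are shortened so the output
#' has the same length as the input. With the default window of 3 this is the
#' smoothing applied to the glucose reference series before labelling.
#'
#' @param x numeric vector.
#' @param window integer >= 1.
#' @return numeric vector, same length as \code{x}.
#' @examples
#' trailingMovingAverage(c(90, 120, 150))  # 90 105 120
#' @export
trailingMovingAverage <- function(x, window = 3L) {
  if (length(x) == 0L) stop("series must be non-empty")
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - window + 1L, 1L)
  (cs[i + 1L] - cs[lo]) / (i - lo + 1L)
}

# Two-layer skin-like sample for a given glucose level. The stratum-corneum
# cover carries the protein bands (1030/1080 cm^-1); the interstitial-fluid
# bulk carries glucose bands (990/1110 cm^-1) whose amplitude scales linearly
# with glucose. glucose_band_coef = 0.06 cm^-1 per mg/dL makes the
# 90 -> 180 mg/dL excursion move the 1110 cm^-1 dip by about 5% of the
# spectral dynamic range.
.skinSample <- function(glucose, glucose_band_coef = 0.06,
                        protein_amp = c(120, 120), glucose_shift = 0,
                        protein_jitter = c(1, 1), glucose_jitter = c(1, 1)) {
  top <- LayerOptics(15, water_fraction = 0.2,
                     bands = absorptionBands(c(1030, 1080) + glucose_shift,
                                             width = 10,
                                             amplitude = protein_amp * protein_jitter))
  bulk <- LayerOptics(1000, water_fraction = 0.8,
                      bands = absorptionBands(c(990, 1110) + glucose_shift,
                                              width = 8,
                                              amplitude = glucose_band_coef *
                                                glucose * glucose_jitter))
  LayeredSample(bulk, top_layer = top)
}

#' Generate a synthetic photoacoustic OGTT dataset
#'
#' Emulates a multi-day measurement campaign: records cycle through the OGTT
#' time course day by day (a 2-h window either side of ingestion at 5-min
#' spacing gives 49 records per day, so e.g. 83 records span two days).
#' Each record's spectrum is synthesized with [synthesizePASSpectrum()] from a
#' two-layer skin-like sample whose glucose band amplitudes at 990 and
#' 1110 cm^-1 scale linearly with that record's reference glucose, then
#' perturbed according to \code{noise}: multiplicative gain jitter, per-band
#' amplitude jitter, additive white noise and a per-day baseline drift.
#' Labels follow [labelByThreshold()] applied to the trailing-3-point-averaged
#' glucose. Fully reproducible from \code{noise$seed}.
#'
#' @param n_records number of measurements, >= 1.
#' @param mode \code{"fixed"} or \code{"repositioned"}.
#' @param ogtt an [ogttParams()] list.
#' @param noise a [noiseParams()] list; its \code{mode} must match.
#' @param grid wavenumber grid inside [930, 1200] cm^-1.
#' @param glucose_band_coef linear glucose-to-band-amplitude coefficient,
#'   cm^-1 per mg/dL.
#' @param threshold hyperglycaemia label threshold, mg/dL.
#' @return a [PASDataset-class] with \code{n_records} columns.
#' @examples
#' ds <- generateDataset(10, noise = noiseParams("fixed", seed = 7))
#' ds
#' @export
generateDataset <- function(n_records, mode = c("fixed", "repositioned"),
                            ogtt = ogttParams(), noise = NULL,
                            grid = defaultGrid(), glucose_band_coef = 0.06,
                            threshold = 140) {
  mode <- match.arg(mode)
  if (is.null(noise)) noise <- noiseParams(mode)
  stopifnot(inherits(ogtt, "OGTTParams"), inherits(noise, "NoiseParams"))
  if (noise$mode != mode)
    stop("noise parameters were built for mode '", noise$mode, "'")
  if (length(n_records) != 1L || is.na(n_records) || n_records < 1L)
    stop("n_records must be >= 1")
  if (length(grid) == 0L || min(grid) < 930 || max(grid) > 1200)
    stop("grid must lie inside [930, 1200] cm^-1")
  n_records <- as.integer(n_records)

  set.seed(noise$seed)
  shift <- if (noise$subject_band_shift_sd > 0)
    rnorm(1, 0, noise$subject_band_shift_sd) else 0

  per_day <- (ogtt$duration_before + ogtt$duration_after) /
    ogtt$sampling_interval + 1L
  n_days <- ceiling(n_records / per_day)

  ts <- g_ref <- g_sm <- day <- numeric(0)
  for (d in seq_len(n_days)) {
    curve <- ogttGlucoseCurve(ogtt, seed = sample.int(.Machine$integer.max, 1))
    sm <- trailingMovingAverage(curve$glucose_mg_dl, 3L)
    ts <- c(ts, curve$time_min)
    g_ref <- c(g_ref, curve$glucose_mg_dl)
    g_sm <- c(g_sm, sm)
    day <- c(day, rep(d, nrow(curve)))
  }
  keep <- seq_len(n_records)
  ts <- ts[keep]; g_ref <- g_ref[keep]; g_sm <- g_sm[keep]; day <- day[keep]

  drift <- rnorm(n_days, 0, noise$baseline_drift_sd)
  spectra <- matrix(0, nrow = length(grid), ncol = n_records)
  for (i in seq_len(n_records)) {
    s <- .skinSample(g_ref[i], glucose_band_coef, glucose_shift = shift,
                     protein_jitter = 1 + rnorm(2, 0, noise$band_amplitude_jitter_sd),
                     glucose_jitter = 1 + rnorm(2, 0, noise$band_amplitude_jitter_sd))
    v <- spectrumValues(synthesizePASSpectrum(s, grid))
    gain <- 1 + rnorm(1, 0, noise$gain_jitter_sd)
    spectra[, i] <- v * gain + drift[day[i]] +
      rnorm(length(grid), 0, noise$additive_sd)
  }
  PASDataset(spectra, grid, ts, g_ref, g_sm,
             labelByThreshold(g_sm, threshold), mode = mode, day = day)
}
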