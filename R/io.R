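#' Read and write spectrum CSV files
#'
#' The spectrum dialect is a two-column UTF-8 CSV with header
#' \code{wavenumber_cm1,value}, one row per grid point, '.' decimal
#' separator; the kind tag travels separately (argument here, sidecar JSON or
#' CLI flag on disk). Round-trips are lossless at full double precision.
#'
#' @param path file path.
#' @param kind kind tag applied to the spectrum read from disk.
#' @param spectrum a [Spectrum-class] to write.
#' @return \code{readSpectrumCSV} returns a [Spectrum-class];
#'   \code{writeSpectrumCSV} returns \code{path} invisibly.
#' @name spectrum_csv
NULL

#' @rdname spectrum_csv
#' @export
readSpectrumCSV <- function(path, kind = "pas_signal_au") {
  df <- read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("wavenumber_cm1", "value")))
    stop("expected header 'wavenumber_cm1,value' in ", path,
         " (line 1); found: ", paste(names(df), collapse = ","))
  bad <- which(!is.finite(df$wavenumber_cm1) | !is.finite(df$value))
  if (length(bad))
    stop("non-finite value in ", path, " at data row ", bad[1],
         " (file line ", bad[1] + 1L, ")")
  nonasc <- which(diff(df$wavenumber_cm1) <= 0)
  if (length(nonasc))
    stop("wavenumber grid not strictly ascending in ", path,
         " at data row ", nonasc[1] + 1L)
  Spectrum(df$wavenumber_cm1, df$value, kind)
}

#' @rdname spectrum_csv
#' @export
writeSpectrumCSV <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  df <- data.frame(wavenumber_cm1 = wavenumbers(spectrum),
                   value = spectrumValues(spectrum))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write frequency-sweep CSV files
#'
#' Header \code{frequency_hz,amplitude}, ascending frequencies.
#'
#' @param path file path.
#' @param sweep a [FrequencySweep-class] to write.
#' @return \code{readSweepCSV} returns a [FrequencySweep-class].
#' @name sweep_csv
NULL

#' @rdname sweep_csv
#' @export
readSweepCSV <- function(path) {
  df <- read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("frequency_hz", "amplitude")))
    stop("expected header 'frequency_hz,amplitude' in ", path)
  FrequencySweep(df$frequency_hz, df$amplitude)
}

#' @rdname sweep_csv
#' @export
writeSweepCSV <- function(sweep, path) {
  stopifnot(is(sweep, "FrequencySweep"))
  df <- data.frame(frequency_hz = sweepFrequencies(sweep),
                   amplitude = sweepAmplitudes(sweep))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write dataset CSV files
#'
#' Wide per-record layout: columns \code{timestamp_min, day, glucose_mg_dl,
#' glucose_smoothed, label, mode}, then one \code{wn_<wavenumber>} column per
#' grid point.
#'
#' @param path file path.
#' @param dataset a [PASDataset-class] to write.
#' @return \code{readDatasetCSV} returns a [PASDataset-class].
#' @name dataset_csv
NULL

.DATASET_META <- c("timestamp_min", "day", "glucose_mg_dl",
                   "glucose_smoothed", "label", "mode")

#' @rdname dataset_csv
#' @export
writeDatasetCSV <- function(dataset, path) {
  stopifnot(is(dataset, "PASDataset"))
  cd <- SummarizedExperiment::colData(dataset)
  sp <- t(spectraMatrix(dataset))
  colnames(sp) <- paste0("wn_", wavenumbers(dataset))
  df <- cbind(data.frame(timestamp_min = cd$timestamp_min, day = cd$day,
                         glucose_mg_dl = cd$glucose_ref,
                         glucose_smoothed = cd$glucose_smoothed,
                         label = cd$label, mode = cd$mode),
              as.data.frame(sp))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname dataset_csv
#' @export
readDatasetCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!all(.DATASET_META %in% names(df)))
    stop("dataset CSV must contain columns: ",
         paste(.DATASET_META, collapse = ", "))
  wn_cols <- grep("^wn_", names(df), value = TRUE)
  if (length(wn_cols) == 0L) stop("no wn_* spectral columns found in ", path)
  wn <- as.numeric(sub("^wn_", "", wn_cols))
  o <- order(wn)
  PASDataset(t(as.matrix(df[, wn_cols[o], drop = FALSE])), wn[o],
             df$timestamp_min, df$glucose_mg_dl, df$glucose_smoothed,
             df$label, mode = df$mode, day = df$day)
}

#' Write a features CSV (label, smoothed glucose, selected band)
#'
#' @param feats list from [preprocessDataset()].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeFeaturesCSV <- function(feats, path) {
  df <- cbind(data.frame(label = feats$y, glucose_smoothed = feats$glucose),
              as.data.frame(feats$X))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a features CSV
#' @param path file path.
#' @return list with \code{X}, \code{y}, \code{glucose}, \code{wavenumbers}.
#' @export
readFeaturesCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wn_cols <- grep("^wn_", names(df), value = TRUE)
  if (!all(c("label", "glucose_smoothed") %in% names(df)) ||
      length(wn_cols) == 0L)
    stop("features CSV must contain label, glucose_smoothed and wn_* columns")
  list(X = as.matrix(df[, wn_cols, drop = FALSE]), y = as.integer(df$label),
       glucose = df$glucose_smoothed,
       wavenumbers = as.numeric(sub("^wn_", "", wn_cols)))
}

#' Serialise and restore a PLS-DA model as JSON
#'
#' Matrices are stored as row-major lists with dimensions, so the round-trip
#' is exact to double precision.
#'
#' @param model a [PLSDAModel-class].
#' @param path JSON file path.
#' @param extra optional named list merged into the JSON (e.g. seeds,
#'   config snapshot).
#' @return \code{readModelJSON} returns a [PLSDAModel-class].
#' @name model_json
NULL

#' @rdname model_json
#' @export
writeModelJSON <- function(model, path, extra = list()) {
  stopifnot(is(model, "PLSDAModel"))
  obj <- c(list(
    x_mean = model@x_mean, y_mean = model@y_mean,
    weights = as.vector(t(model@weights)),
    loadings = as.vector(t(model@loadings)),
    y_loadings = model@y_loadings,
    regression_vector = model@regression_vector,
    n_latent = model@n_latent, n_features = length(model@x_mean),
    decision_threshold = model@decision_threshold), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_json
#' @export
readModelJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- o$n_features; A <- o$n_latent
  new("PLSDAModel", x_mean = o$x_mean, y_mean = o$y_mean,
      weights = matrix(o$weights, p, A, byrow = TRUE),
      loadings = matrix(o$loadings, p, A, byrow = TRUE),
      y_loadings = as.numeric(o$y_loadings),
      regression_vector = o$regression_vector, n_latent = as.integer(A),
      decision_threshold = o$decision_threshold)
}

#' Write a run manifest
#'
#' Records tool version, timestamp, subcommand, full parameter snapshot,
#' seeds and MD5 digests of inputs/outputs, sufficient to reproduce a
#' stochastic run bit-exactly.
#'
#' @param path JSON file path.
#' @param subcommand character tag of the pipeline stage.
#' @param params named list of parameters (including all seeds).
#' @param files character vector of input/output paths to digest.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(path, subcommand, params, files = character()) {
  digests <- if (length(files))
    setNames(as.character(tools::md5sum(files)), basename(files))
  else NULL
  jsonlite::write_json(list(
    tool = "pzpas", version = as.character(utils::packageVersion("pzpas")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    subcommand = subcommand, params = params, digests = digests),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
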