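#' Photoacoustic spectral dataset
#'
#' A \code{PASDataset} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: the \code{"spectra"}
#' assay holds one photoacoustic spectrum per column (rows = wavenumber grid,
#' stored in \code{rowData()$wavenumber_cm1}), and \code{colData()} carries
#' per-measurement metadata: \code{timestamp_min} (minutes relative to glucose
#' ingestion), \code{day}, reference and smoothed glucose (mg/dL), the 0/1
#' hyperglycaemia label and the acquisition mode (\code{"fixed"} or
#' \code{"repositioned"}).
#'
#' @aliases PASDataset
#' @export
setClass("PASDataset", contains = "SummarizedExperiment")

.PASDATASET_COLS <- c("timestamp_min", "day", "glucose_ref",
                      "glucose_smoothed", "label", "mode")

setValidity("PASDataset", function(object) {
  msg <- character()
  if (!"spectra" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'spectra' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"wavenumber_cm1" %in% names(rd))
    msg <- c(msg, "rowData must contain wavenumber_cm1")
  else {
    wn <- rd$wavenumber_cm1
    if (length(wn) > 1L && any(diff(wn) <= 0))
      msg <- c(msg, "wavenumber grid must be strictly ascending")
  }
  cd <- SummarizedExperiment::colData(object)
  missing_cols <- setdiff(.PASDATASET_COLS, names(cd))
  if (length(missing_cols))
    msg <- c(msg, paste("colData is missing:", paste(missing_cols, collapse = ", ")))
  if ("label" %in% names(cd) && !all(cd$label %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if ("mode" %in% names(cd) && !all(cd$mode %in% c("fixed", "repositioned")))
    msg <- c(msg, "mode must be 'fixed' or 'repositioned'")
  if (length(msg)) msg else TRUE
})

#' Construct a PASDataset
#'
#' @param spectra numeric matrix, wavenumbers x records.
#' @param wavenumbers ascending grid in cm^-1, one per row of \code{spectra}.
#' @param timestamp_min minutes relative to glucose ingestion, one per record.
#' @param glucose_ref,glucose_smoothed reference and trailing-averaged glucose
#'   in mg/dL.
#' @param label 0/1 class label (glucose above the 140 mg/dL threshold).
#' @param mode \code{"fixed"} or \code{"repositioned"} (recycled).
#' @param day acquisition day index (recycled, default 1).
#' @return a [PASDataset-class].
#' @export
PASDataset <- function(spectra, wavenumbers, timestamp_min, glucose_ref,
                       glucose_smoothed, label, mode = "fixed", day = 1L) {
  n <- ncol(spectra)
  cd <- S4Vectors::DataFrame(
    timestamp_min = as.numeric(timestamp_min),
    day = rep_len(as.integer(day), n),
    glucose_ref = as.numeric(glucose_ref),
    glucose_smoothed = as.numeric(glucose_smoothed),
    label = as.integer(label),
    mode = rep_len(as.character(mode), n))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectra = spectra),
    rowData = S4Vectors::DataFrame(wavenumber_cm1 = as.numeric(wavenumbers)),
    colData = cd)
  new("PASDataset", se)
}

#' @rdname accessors
#' @export
setMethod("wavenumbers", "PASDataset", function(x)
  SummarizedExperiment::rowData(x)$wavenumber_cm1)

#' @rdname accessors
#' @export
setMethod("spectraMatrix", "PASDataset", function(x)
  SummarizedExperiment::assay(x, "spectra"))

#' @rdname accessors
#' @export
setMethod("glucoseRef", "PASDataset", function(x)
  SummarizedExperiment::colData(x)$glucose_ref)

#' @rdname accessors
#' @export
setMethod("glucoseSmoothed", "PASDataset", function(x)
  SummarizedExperiment::colData(x)$glucose_smoothed)

#' @rdname accessors
#' @export
setMethod("classLabels", "PASDataset", function(x)
  SummarizedExperiment::colData(x)$label)

#' @rdname accessors
#' @export
setMethod("acquisitionMode", "PASDataset", function(x)
  SummarizedExperiment::colData(x)$mode)

setMethod("show", "PASDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  wn <- wavenumbers(object)
  cat(sprintf("PASDataset: %d spectra x %d wavenumbers (%.0f-%.0f cm-1)\n",
              ncol(object), nrow(object), min(wn), max(wn)))
  cat(sprintf("  mode: %s; days: %d; labels: %d low / %d high\n",
              paste(unique(cd$mode), collapse = "+"),
              length(unique(cd$day)),
              sum(cd$label == 0L), sum(cd$label == 1L)))
})
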