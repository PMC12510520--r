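#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: wavenumber grids,
#' spectral values, sweep frequencies/amplitudes and per-record metadata of a
#' [PASDataset-class].
#'
#' @param x an object of the documented classes.
#' @return the requested component (numeric vector, matrix or factor).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("spectrumValues", function(x) standardGeneric("spectrumValues"))

#' @rdname accessors
#' @export
setGeneric("spectrumKind", function(x) standardGeneric("spectrumKind"))

#' @rdname accessors
#' @export
setGeneric("sweepFrequencies", function(x) standardGeneric("sweepFrequencies"))

#' @rdname accessors
#' @export
setGeneric("sweepAmplitudes", function(x) standardGeneric("sweepAmplitudes"))

#' @rdname accessors
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname accessors
#' @export
setGeneric("glucoseRef", function(x) standardGeneric("glucoseRef"))

#' @rdname accessors
#' @export
setGeneric("glucoseSmoothed", function(x) standardGeneric("glucoseSmoothed"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("acquisitionMode", function(x) standardGeneric("acquisitionMode"))

#' @rdname accessors
#' @export
setMethod("wavenumbers", "Spectrum", function(x) x@wavenumbers)

#' @rdname accessors
#' @export
setMethod("spectrumValues", "Spectrum", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("spectrumKind", "Spectrum", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("sweepFrequencies", "FrequencySweep", function(x) x@frequencies)

#' @rdname accessors
#' @export
setMethod("sweepAmplitudes", "FrequencySweep", function(x) x@amplitudes)
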