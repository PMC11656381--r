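#' Accessors for Spectrum and result classes
#'
#' `xValues()` and `intensity()` return the abscissa and intensity of a
#' [Spectrum-class]; `peaks()` the peak table of a [PeakSet-class];
#' `components()` the profile table of a [Decomposition-class];
#' `baselineVector()` the estimated baseline of a [BaselineResult-class].
#'
#' @param object the object to access.
#' @return The underlying vector or data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("xValues", function(object) standardGeneric("xValues"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("components", function(object) standardGeneric("components"))

#' @rdname accessors
#' @export
setGeneric("baselineVector", function(object) standardGeneric("baselineVector"))

#' @rdname accessors
setMethod("xValues", "Spectrum", function(object) object@x)

#' @rdname accessors
setMethod("intensity", "Spectrum", function(object) object@y)

#' @rdname accessors
setMethod("peaks", "PeakSet", function(object) object@peaks)

#' @rdname accessors
setMethod("components", "Decomposition", function(object) object@components)

#' @rdname accessors
setMethod("baselineVector", "BaselineResult", function(object) object@z)

#' @rdname accessors
#' @export
setMethod("length", "Spectrum", function(x) length(x@x))

#' @rdname accessors
#' @export
setMethod("length", "PeakSet", function(x) nrow(x@peaks))
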