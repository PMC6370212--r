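#' @include AllClasses.R
NULL

#' @rdname BuildingBlockLibrary-class
#' @param object,x an object.
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname Composition-class
#' @export
setGeneric("aglycone", function(x) standardGeneric("aglycone"))

#' @rdname Composition-class
#' @export
setGeneric("decorations", function(x) standardGeneric("decorations"))

#' @rdname Composition-class
#' @export
setGeneric("cationMz", function(x) standardGeneric("cationMz"))

#' @rdname Composition-class
#' @export
setGeneric("totalFormula", function(x) standardGeneric("totalFormula"))

#' @rdname Spectrum-class
#' @export
setGeneric("spectrumId", function(x) standardGeneric("spectrumId"))

#' @rdname Spectrum-class
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @rdname Spectrum-class
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname Annotation-class
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname Annotation-class
#' @export
setGeneric("bestCandidate", function(x) standardGeneric("bestCandidate"))
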