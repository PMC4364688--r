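#' Accessors for panel, map and mask objects
#'
#' Small accessor generics used throughout the package instead of direct
#' slot access: marker/line identifiers, call and dosage matrices, mask
#' states, and panel dimensions.
#'
#' @param x an object of one of the package's classes.
#' @return the corresponding slot content (see methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname accessors
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("maskStates", function(x) standardGeneric("maskStates"))

#' @rdname accessors
#' @export
setGeneric("truthCalls", function(x) standardGeneric("truthCalls"))

#' @rdname accessors
#' @export
setGeneric("nLines", function(x) standardGeneric("nLines"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("highSet", function(x) standardGeneric("highSet"))

#' @rdname accessors
#' @export
setGeneric("lowSet", function(x) standardGeneric("lowSet"))

#' @rdname accessors
#' @export
setGeneric("imputeSet", function(x) standardGeneric("imputeSet"))

#' @rdname accessors
#' @export
setGeneric("refLines", function(x) standardGeneric("refLines"))

#' @rdname accessors
#' @export
setGeneric("testLines", function(x) standardGeneric("testLines"))

#' @rdname accessors
#' @export
setGeneric("scenario", function(x) standardGeneric("scenario"))
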