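#' @include AllClasses.R
NULL

#' Accessors for pose and annotation objects
#'
#' Small generic accessor family; slot access from user code is discouraged.
#'
#' @param x,object an object of the relevant class.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("entryPoint", function(x) standardGeneric("entryPoint"))
#' @rdname accessors
#' @export
setGeneric("hingePoint", function(x) standardGeneric("hingePoint"))
#' @rdname accessors
#' @export
setGeneric("tipPoints", function(x) standardGeneric("tipPoints"))
#' @rdname accessors
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))
#' @rdname accessors
#' @export
setGeneric("instanceId", function(x) standardGeneric("instanceId"))
#' @rdname accessors
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))
#' @rdname accessors
#' @export
setGeneric("frameSize", function(x) standardGeneric("frameSize"))
#' @rdname accessors
#' @export
setGeneric("poses", function(x) standardGeneric("poses"))
#' @rdname accessors
#' @export
setGeneric("keypointTriplets", function(x) standardGeneric("keypointTriplets"))
#' @rdname accessors
#' @export
setGeneric("bboxVector", function(x) standardGeneric("bboxVector"))
#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname summaryTable
#' @export
setGeneric("summaryTable", function(x, ...) standardGeneric("summaryTable"))
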