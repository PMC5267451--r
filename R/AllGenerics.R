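#' @rdname SVCallSet-accessors
#' @export
setGeneric("svCalls", function(x) standardGeneric("svCalls"))

#' @rdname SVCallSet-accessors
#' @export
setGeneric("svLabel", function(x) standardGeneric("svLabel"))

#' @rdname SVCallSet-accessors
#' @export
setGeneric("svType", function(x) standardGeneric("svType"))

#' @rdname SVCallSet-accessors
#' @export
setGeneric("svLength", function(x) standardGeneric("svLength"))

#' @rdname SVCallSet-accessors
#' @export
setGeneric("svSupport", function(x) standardGeneric("svSupport"))

#' @rdname SVCallSet-accessors
#' @export
setGeneric("svSample", function(x) standardGeneric("svSample"))

#' @rdname SVCallSet-accessors
#' @export
setGeneric("svCaller", function(x) standardGeneric("svCaller"))

#' @rdname SVCallSet-accessors
#' @export
setGeneric("svGenotype", function(x) standardGeneric("svGenotype"))

#' @rdname SVCallSet-accessors
#' @export
setGeneric("splitBySample", function(x) standardGeneric("splitBySample"))

#' @rdname unionCoveredLength
#' @export
setGeneric("unionCoveredLength", function(x, ...)
    standardGeneric("unionCoveredLength"))
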