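#' Accessors for SVCallSet objects
#'
#' \code{svCalls} returns the underlying \code{GRanges} (with all metadata
#' columns); \code{svLabel} the set label; the remaining accessors return the
#' per-record metadata vectors.  \code{splitBySample} splits a set into a named
#' list of per-sample \code{SVCallSet}s.
#'
#' @param x an \code{SVCallSet}.
#' @return see Description.
#' @name SVCallSet-accessors
#' @aliases svCalls svLabel svType svLength svSupport svSample svCaller
#'   svGenotype splitBySample
NULL

#' @rdname SVCallSet-accessors
#' @export
setMethod("svCalls", "SVCallSet", function(x) x@calls)

#' @rdname SVCallSet-accessors
#' @export
setMethod("svLabel", "SVCallSet", function(x) x@label)

#' @rdname SVCallSet-accessors
#' @export
setMethod("svType", "SVCallSet", function(x) mcols(x@calls)$svtype)

#' @rdname SVCallSet-accessors
#' @export
setMethod("svLength", "SVCallSet", function(x) mcols(x@calls)$svlen)

#' @rdname SVCallSet-accessors
#' @export
setMethod("svSupport", "SVCallSet", function(x) mcols(x@calls)$support)

#' @rdname SVCallSet-accessors
#' @export
setMethod("svSample", "SVCallSet", function(x) mcols(x@calls)$sample)

#' @rdname SVCallSet-accessors
#' @export
setMethod("svCaller", "SVCallSet", function(x) mcols(x@calls)$caller)

#' @rdname SVCallSet-accessors
#' @export
setMethod("svGenotype", "SVCallSet", function(x) mcols(x@calls)$genotype)

#' @export
setMethod("length", "SVCallSet", function(x) length(x@calls))

#' @export
setMethod("[", "SVCallSet", function(x, i, j, ..., drop = TRUE) {
    ## an SVCallSet is a sorted container: subsetting re-sorts
    gr <- x@calls[i]
    initialize(x, calls = gr[order(gr)])
})

#' @rdname SVCallSet-accessors
#' @export
setMethod("splitBySample", "SVCallSet", function(x) {
    ids <- sort(unique(svSample(x)))
    out <- lapply(ids, function(s) x[svSample(x) == s])
    names(out) <- ids
    out
})

#' @export
setMethod("show", "SVCallSet", function(object) {
    cat(sprintf("SVCallSet '%s': %d records, %d sample(s)\n",
                svLabel(object), length(object),
                length(unique(svSample(object)))))
    if (length(object)) {
        tab <- table(factor(svType(object), levels = .SV_TYPES))
        cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                        collapse = "  "), "\n", sep = "")
    }
})
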