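#' Pairwise overlap length of genomic intervals
#'
#' Length, in bp, of the intersection of two intervals taken element-wise.
#' Intervals on different chromosomes overlap by 0 bp; abutting intervals
#' (one ends where the next starts minus one) overlap by 0 bp.
#'
#' @param a,b \code{GRanges} of equal length (or either of length 1, recycled).
#' @return integer vector of overlap lengths in bp.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' overlapLength(a, b)  # 50
#' @export
overlapLength <- function(a, b) {
    if (length(a) != length(b)) {
        if (length(a) == 1L) a <- rep(a, length(b))
        else if (length(b) == 1L) b <- rep(b, length(a))
        else stop("'a' and 'b' must have equal length (or length 1)")
    }
    w <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
    w[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
    pmax(w, 0L)
}

#' Fraction of a truth SV covered by a call
#'
#' For deletions, inversions and duplications the fraction is the overlap
#' length divided by the truth SV's length.  Insertions occupy no reference
#' span, so two insertions "overlap" when their breakpoints lie within
#' \code{insWindow} bp of each other: the fraction is then 1, otherwise 0.
#' With \code{mode = "reciprocal"} the reported fraction is the smaller of the
#' two relative overlaps, so a match requires the threshold in both directions.
#'
#' @param call,truth \code{SVCallSet}s or \code{GRanges} with \code{svtype} and
#'   \code{svlen} metadata columns, compared element-wise (recycled if one has
#'   length 1).  Records whose types differ get fraction 0.
#' @param insWindow breakpoint window for insertions, bp.
#' @param mode \code{"truth"} (fraction of the truth SV, the default) or
#'   \code{"reciprocal"}.
#' @return numeric vector of fractions in [0, 1].
#' @export
overlapFractionOfTruth <- function(call, truth, insWindow = 25,
                                   mode = c("truth", "reciprocal")) {
    mode <- match.arg(mode)
    if (is(call, "SVCallSet")) call <- svCalls(call)
    if (is(truth, "SVCallSet")) truth <- svCalls(truth)
    if (length(call) != length(truth)) {
        if (length(call) == 1L) call <- rep(call, length(truth))
        else if (length(truth) == 1L) truth <- rep(truth, length(call))
        else stop("'call' and 'truth' must have equal length (or length 1)")
    }
    tc <- mcols(call)$svtype
    tt <- mcols(truth)$svtype
    ins <- tt == "INS"
    if (any(!ins & mcols(truth)$svlen <= 0))
        stop("truth record of zero length for a non-INS type")
    frac <- numeric(length(call))
    if (any(!ins)) {
        ov <- overlapLength(call[!ins], truth[!ins])
        ft <- ov / mcols(truth)$svlen[!ins]
        if (mode == "reciprocal") {
            lc <- mcols(call)$svlen[!ins]
            ft <- pmin(ft, ifelse(lc > 0, ov / lc, 0))
        }
        frac[!ins] <- ft
    }
    if (any(ins)) {
        hit <- abs(start(call)[ins] - start(truth)[ins]) <= insWindow &
            as.character(seqnames(call))[ins] ==
            as.character(seqnames(truth))[ins]
        frac[ins] <- as.numeric(hit)
    }
    frac[tc != tt] <- 0
    pmin(pmax(frac, 0), 1)
}

#' Total genome length covered by a set of SV
#'
#' Per-chromosome union of the reference spans of all non-insertion records,
#' plus the summed inserted lengths of insertion records (which occupy no
#' reference span but contribute sequence).  Duplicate records do not count
#' twice.
#'
#' @param x an \code{SVCallSet}, or a plain \code{GRanges} (treated as
#'   reference intervals only).
#' @param ... unused.
#' @return covered length in bp (a single number).
#' @seealso \code{\link{coveredLengthByType}}
#' @rdname unionCoveredLength
#' @export
setMethod("unionCoveredLength", "SVCallSet", function(x, ...) {
    gr <- svCalls(x)
    ins <- svType(x) == "INS"
    sum(width(reduce(granges(gr[!ins])))) + sum(svLength(x)[ins])
})

#' @rdname unionCoveredLength
#' @export
setMethod("unionCoveredLength", "GRanges", function(x, ...) {
    sum(width(reduce(granges(x))))
})

#' Covered length split by SV type
#'
#' @param x an \code{SVCallSet}.
#' @return named numeric vector (DEL/INS/INV/DUP) of covered bp.
#' @export
coveredLengthByType <- function(x) {
    stopifnot(is(x, "SVCallSet"))
    vapply(.SV_TYPES, function(tp) {
        unionCoveredLength(x[svType(x) == tp])
    }, numeric(1))
}

#' Reduced reference regions covered by a call set
#'
#' @param x an \code{SVCallSet}.
#' @param types SV types to include (insertions never contribute reference
#'   span and are always excluded).
#' @return a reduced \code{GRanges}.
#' @export
coveredRegions <- function(x, types = c("DEL", "INV", "DUP")) {
    stopifnot(is(x, "SVCallSet"))
    keep <- svType(x) %in% setdiff(types, "INS")
    reduce(granges(svCalls(x)[keep]))
}
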