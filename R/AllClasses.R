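#' SVCallSet: a labelled collection of structural-variant calls
#'
#' An \code{SVCallSet} holds the SV records of one analysis unit (a caller run,
#' a sample, a population set) as a sorted \code{\link[GenomicRanges]{GRanges}}
#' with the metadata columns \code{svtype} (DEL/INS/INV/DUP), \code{svlen}
#' (event length in bp), \code{support} (supporting read pairs / split reads),
#' \code{sample}, \code{caller} and \code{genotype} (HOM/HET/UNKNOWN).
#'
#' Coordinates are 1-based closed (the native \code{GRanges} convention); an
#' insertion occupies a single reference base at its breakpoint (width 1) and
#' carries the inserted length in \code{svlen}.  For the other types
#' \code{svlen} always equals the reference span.
#'
#' @slot label single string naming the set (e.g. \code{"POP_A"}).
#' @slot calls \code{GRanges} of SV records, sorted by (chromosome, start, end).
#'
#' @aliases SVCallSet-class
#' @seealso \code{\link{svCalls}}, \code{\link{svType}},
#'   \code{\link{unionCoveredLength}}
#' @export
setClass("SVCallSet",
         slots = c(label = "character", calls = "GRanges"))

.REQUIRED_MCOLS <- c("svtype", "svlen", "support", "sample", "caller",
                     "genotype")

setValidity("SVCallSet", function(object) {
    msg <- character()
    if (length(object@label) != 1L || is.na(object@label))
        msg <- c(msg, "'label' must be a single non-NA string")
    gr <- object@calls
    mc <- mcols(gr)
    missing <- setdiff(.REQUIRED_MCOLS, colnames(mc))
    if (length(missing))
        return(paste("missing metadata columns:",
                     paste(missing, collapse = ", ")))
    if (length(gr)) {
        if (!all(mc$svtype %in% .SV_TYPES))
            msg <- c(msg, sprintf("svtype must be one of %s",
                                  paste(.SV_TYPES, collapse = "/")))
        if (!all(mc$genotype %in% .GENOTYPES))
            msg <- c(msg, sprintf("genotype must be one of %s",
                                  paste(.GENOTYPES, collapse = "/")))
        if (anyNA(mc$support) || any(mc$support < 0))
            msg <- c(msg, "support must be a non-negative count")
        if (any(start(gr) < 1))
            msg <- c(msg, "start positions must be >= 1")
        ins <- mc$svtype == "INS"
        if (any(ins)) {
            if (any(width(gr)[ins] != 1L))
                msg <- c(msg, "INS records must have width 1 (breakpoint)")
            if (any(mc$svlen[ins] < 1))
                msg <- c(msg, "INS records must have svlen >= 1")
        }
        if (any(!ins) && any(mc$svlen[!ins] != width(gr)[!ins]))
            msg <- c(msg, "svlen must equal the reference span for non-INS records")
        if (is.unsorted(order(gr)))
            msg <- c(msg, "records must be sorted by (chrom, start, end)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an SVCallSet
#'
#' @param calls a \code{GRanges}; metadata columns not supplied through the
#'   arguments below must already be present on \code{calls}.
#' @param label single string naming the set.
#' @param svtype,svlen,support,sample,caller,genotype optional per-record
#'   vectors (recycled) filling the corresponding metadata columns.
#'   \code{svlen} defaults to the reference span for non-INS records and is
#'   mandatory for INS records.
#' @return a validated, sorted \code{SVCallSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' SVCallSet(gr, label = "toy", svtype = "DEL", support = 10L)
#' @export
SVCallSet <- function(calls = GRanges(), label = "callset", svtype = NULL,
                      svlen = NULL, support = NULL, sample = NULL,
                      caller = NULL, genotype = NULL) {
    if (!is(calls, "GRanges"))
        stop("'calls' must be a GRanges")
    gr <- granges(calls)
    mcols(gr) <- mcols(calls)
    strand(gr) <- "*"
    n <- length(gr)
    fill <- function(given, name, default) {
        if (!is.null(given)) rep(given, length.out = n)
        else if (name %in% colnames(mcols(gr))) mcols(gr)[[name]]
        else rep(default, length.out = n)
    }
    svtype <- as.character(fill(svtype, "svtype",
                                if (n) stop("'svtype' is required") else character()))
    support <- as.integer(fill(support, "support", 0L))
    sample <- as.character(fill(sample, "sample", "sample1"))
    caller <- as.character(fill(caller, "caller", "unknown"))
    genotype <- as.character(fill(genotype, "genotype", "UNKNOWN"))
    svlen <- fill(svlen, "svlen", NA_real_)
    if (n) {
        ins <- svtype == "INS"
        svlen[!ins] <- width(gr)[!ins]
        if (anyNA(svlen[ins]))
            stop("'svlen' must be given for INS records")
    }
    mcols(gr) <- DataFrame(svtype = svtype, svlen = as.numeric(svlen),
                           support = support, sample = sample,
                           caller = caller, genotype = genotype)
    gr <- sortSeqlevels(gr)
    gr <- gr[order(gr)]
    new("SVCallSet", label = label, calls = gr)
}
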