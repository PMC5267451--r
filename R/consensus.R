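#' Filter raw caller output for the population pipeline
#'
#' Applies, in order: (1) the minimum supporting-read threshold; (2) exclusion
#' of every record that overlaps an assembly-gap region by at least 1 bp;
#' (3) optionally, a per-type cap on supporting reads of
#' \code{maxSupportMultiplier[svtype]} times the sample's genome coverage
#' (guards split-read callers against collapsed-repeat pile-ups; duplications
#' legitimately attract more reads, hence their higher multiplier);
#' (4) the recurrence filter: records are clustered across samples (same type,
#' at least \code{reciprocalFraction} reciprocal overlap; insertion breakpoints
#' within \code{insWindow} bp) and clusters observed in fewer than
#' \code{minIndividuals} distinct samples are dropped.
#'
#' The operation is idempotent: filtering an already filtered set changes
#' nothing.
#'
#' @param x an \code{SVCallSet} indexed by sample.
#' @param gaps \code{GRanges} of assembly gaps, or NULL to skip gap filtering.
#' @param minSupport minimum supporting reads (default 4).
#' @param minIndividuals minimum number of distinct samples carrying the SV
#'   (default 2); 1 disables the recurrence filter.
#' @param coverage named numeric vector, mean fold-coverage per sample;
#'   required when \code{applyMaxSupport} is TRUE.
#' @param applyMaxSupport apply the maximum-support cap (intended for
#'   split-read-style call sets).
#' @param maxSupportMultiplier per-type coverage multipliers for the cap.
#' @param reciprocalFraction reciprocal-overlap fraction used to decide that
#'   two samples carry the same SV (default 0.5).
#' @param insWindow insertion breakpoint window, bp.
#' @return the filtered \code{SVCallSet}.
#' @export
filterRawCalls <- function(x, gaps = NULL, minSupport = 4,
                           minIndividuals = 2, coverage = NULL,
                           applyMaxSupport = FALSE,
                           maxSupportMultiplier = c(DEL = 2, INS = 2,
                                                    INV = 2, DUP = 4),
                           reciprocalFraction = 0.5, insWindow = 25) {
    stopifnot(is(x, "SVCallSet"))
    gr <- svCalls(x)
    keep <- mcols(gr)$support >= minSupport
    gr <- gr[keep]
    if (!is.null(gaps) && length(gr))
        gr <- gr[countOverlaps(gr, gaps) == 0]
    if (applyMaxSupport && length(gr)) {
        samples <- unique(mcols(gr)$sample)
        if (is.null(coverage) || !all(samples %in% names(coverage)))
            stop("missing coverage for sample(s): ",
                 paste(setdiff(samples, names(coverage)), collapse = ", "))
        cap <- maxSupportMultiplier[mcols(gr)$svtype] *
            coverage[mcols(gr)$sample]
        gr <- gr[mcols(gr)$support <= cap]
    }
    if (minIndividuals > 1 && length(gr)) {
        comp <- .clusterRecords(gr, frac = reciprocalFraction,
                                insWindow = insWindow)
        nsamp <- vapply(split(mcols(gr)$sample, comp),
                        function(s) length(unique(s)), integer(1))
        gr <- gr[nsamp[as.character(comp)] >= minIndividuals]
    }
    SVCallSet(gr, label = svLabel(x))
}

#' Dual-caller consensus set
#'
#' Intersects two call sets: records of equal SV type, from the same sample,
#' overlapping by at least \code{minOverlap} bp (insertions: breakpoints within
#' \code{insWindow} bp) are matched one-to-one, greedily by descending overlap
#' with a deterministic positional tie-break, so the result does not depend on
#' input record order.  Each matched pair emits one consensus record spanning
#' the intersection, with the smaller of the two supporting-read counts.
#'
#' @param a,b \code{SVCallSet}s from the two callers over the same samples.
#' @param minOverlap minimum overlap, bp (default 25).
#' @param insWindow insertion breakpoint window, bp (default 25).
#' @param label label of the consensus set.
#' @return an \code{SVCallSet} with \code{caller == label}.
#' @export
intersectCallers <- function(a, b, minOverlap = 25, insWindow = 25,
                             label = "consensus") {
    stopifnot(is(a, "SVCallSet"), is(b, "SVCallSet"))
    grA <- svCalls(a)
    grB <- svCalls(b)
    pairs <- .greedySelect(
        .pairCandidates(grA, grB, minOverlap, insWindow,
                        requireSample = TRUE),
        grA, grB)
    SVCallSet(.consensusRecords(grA, grB, pairs, label), label = label)
}

#' Per-type SV counts and covered genome length
#'
#' Number of records and union covered length (bp) per SV type, plus totals.
#' The total covered length is the sum of the four per-type covered lengths;
#' types are deliberately not unioned across each other, so a region carrying
#' both a deletion and a duplication counts once per type.
#'
#' @param x an \code{SVCallSet}.
#' @return \code{data.frame} with columns \code{svtype}, \code{n},
#'   \code{covered_bp}; the last row is the total.
#' @export
populationSummary <- function(x) {
    stopifnot(is(x, "SVCallSet"))
    cov <- coveredLengthByType(x)
    n <- vapply(.SV_TYPES, function(tp) sum(svType(x) == tp), integer(1))
    data.frame(svtype = c(.SV_TYPES, "total"),
               n = c(n, sum(n)),
               covered_bp = c(cov, sum(cov)),
               row.names = NULL)
}

#' Genome coverage shared between two call sets
#'
#' Per SV type, the length of the intersection of the two sets' covered
#' regions.  For insertions (no reference span) matched breakpoint pairs
#' (within \code{insWindow} bp) contribute the smaller inserted length.
#' Fractions are the shared total over each set's total covered length.
#'
#' @param a,b \code{SVCallSet}s.
#' @param insWindow insertion breakpoint window, bp.
#' @return list with \code{by_type} (named bp vector), \code{shared_bp},
#'   \code{fraction_of_a}, \code{fraction_of_b}.
#' @export
sharedCoverage <- function(a, b, insWindow = 25) {
    stopifnot(is(a, "SVCallSet"), is(b, "SVCallSet"))
    byType <- vapply(.SV_TYPES, function(tp) {
        if (tp == "INS") {
            ai <- a[svType(a) == "INS"]
            bi <- b[svType(b) == "INS"]
            m <- .matchCallSets(ai, bi, minOverlap = 1, insWindow = insWindow)
            if (!nrow(m)) 0
            else sum(pmin(svLength(ai)[m$i], svLength(bi)[m$j]))
        } else {
            ra <- coveredRegions(a, tp)
            rb <- coveredRegions(b, tp)
            .intersectionLength(ra, rb)
        }
    }, numeric(1))
    totA <- sum(coveredLengthByType(a))
    totB <- sum(coveredLengthByType(b))
    shared <- sum(byType)
    list(by_type = byType,
         shared_bp = shared,
         fraction_of_a = if (totA > 0) shared / totA else NA_real_,
         fraction_of_b = if (totB > 0) shared / totB else NA_real_)
}

#' Test observed dual-caller overlap against chance expectation
#'
#' Under independent placement, the chance expectation for the proportion of a
#' chromosome covered by both callers is the product of the two callers'
#' per-chromosome coverage proportions.  The observed overlap proportions are
#' compared to these expectations with a paired t-test across chromosomes
#' (one-sided by default: observed greater than expected).
#'
#' @param covA,covB named numeric vectors, proportion of each chromosome
#'   covered by caller A and caller B.
#' @param observed named numeric vector, proportion of each chromosome covered
#'   by the overlap of the two callers.
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"}.
#' @return list with \code{statistic}, \code{p.value}, \code{df},
#'   \code{expected}.
#' @export
expectedOverlapTest <- function(covA, covB, observed,
                                alternative = c("greater", "less",
                                                "two.sided")) {
    alternative <- match.arg(alternative)
    if (!is.null(names(covA))) {
        if (is.null(names(covB)) || is.null(names(observed)) ||
            !setequal(names(covA), names(covB)) ||
            !setequal(names(covA), names(observed)))
            stop("'covA', 'covB' and 'observed' must cover the same chromosomes")
        covB <- covB[names(covA)]
        observed <- observed[names(covA)]
    }
    if (length(covA) < 2)
        stop("need at least two chromosomes")
    expected <- covA * covB
    if (sd(observed - expected) == 0)
        stop("degenerate t-test: zero variance of differences")
    tt <- t.test(observed, expected, paired = TRUE, alternative = alternative)
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
         df = unname(tt$parameter), expected = expected)
}
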