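#' Twice-sequenced replicate validation
#'
#' Two independent sequencing runs of one individual should support the same
#' SV; only records detected in both replicate call sets are kept.  Matching is
#' one-to-one by SV type with at least \code{minOverlap} bp overlap (insertion
#' breakpoints within \code{insWindow} bp); each match emits a consensus record
#' spanning the intersection.
#'
#' @param rep1,rep2 \code{SVCallSet}s from the two runs of the same individual.
#' @param minOverlap minimum overlap, bp.
#' @param insWindow insertion breakpoint window, bp.
#' @param label label of the validated set.
#' @return an \code{SVCallSet} of replicate-validated records.
#' @export
twiceSequencedValidate <- function(rep1, rep2, minOverlap = 25,
                                   insWindow = 25, label = "TWICE_SEQ") {
    stopifnot(is(rep1, "SVCallSet"), is(rep2, "SVCallSet"))
    grA <- svCalls(rep1)
    grB <- svCalls(rep2)
    pairs <- .greedySelect(
        .pairCandidates(grA, grB, minOverlap, insWindow,
                        requireSample = FALSE),
        grA, grB)
    SVCallSet(.consensusRecords(grA, grB, pairs, label), label = label)
}

#' Concordance between merged-evidence and replicate-overlap call sets
#'
#' For a twice-sequenced individual, compares the call set obtained from the
#' pooled evidence of both runs (\code{mergeSet}) with the replicate-overlap
#' set (\code{overlapSet}).  \code{SHARE} is the number of one-to-one matched
#' records and the concordance is
#' \code{SHARE / min(n_merge, n_overlap) * 100}.
#'
#' @param mergeSet,overlapSet \code{SVCallSet}s for the same individual.
#' @param minOverlap minimum overlap, bp.
#' @param insWindow insertion breakpoint window, bp.
#' @return list with \code{merge_count}, \code{overlap_count},
#'   \code{shared_count}, \code{overlap_percent}.
#' @export
mergeOverlapConcordance <- function(mergeSet, overlapSet, minOverlap = 25,
                                    insWindow = 25) {
    stopifnot(is(mergeSet, "SVCallSet"), is(overlapSet, "SVCallSet"))
    m <- length(mergeSet)
    o <- length(overlapSet)
    if (m == 0 && o == 0)
        stop("both call sets are empty")
    share <- nrow(.matchCallSets(mergeSet, overlapSet, minOverlap, insWindow))
    pct <- if (min(m, o) > 0) share / min(m, o) * 100 else {
        warning("one call set is empty; concordance undefined")
        NA_real_
    }
    list(merge_count = m, overlap_count = o, shared_count = share,
         overlap_percent = pct)
}

#' Sire-son transmission validation
#'
#' An SV allele carried by a sire is transmitted to each son with probability 1
#' (homozygous sire) or 0.5 (heterozygous sire), so a son SV that matches an SV
#' in his sire's call set is consistent with Mendelian inheritance.  Every son
#' record matching a sire record (same type, at least \code{minOverlap} bp;
#' insertion breakpoints within \code{insWindow} bp) in at least one pair is
#' reported; records validated in several pairs are de-duplicated by
#' reciprocal-overlap clustering (one representative per cluster).
#'
#' @param callsets named list of \code{SVCallSet}s, one per sample.
#' @param pedigree \code{data.frame} with columns \code{son}, \code{sire}
#'   (see \code{\link{readPedigree}}).  Pairs whose samples are missing from
#'   \code{callsets} are skipped with a warning.
#' @param minOverlap minimum overlap, bp.
#' @param insWindow insertion breakpoint window, bp.
#' @param reciprocalFraction clustering threshold for cross-pair
#'   de-duplication.
#' @param label label of the validated set.
#' @return an \code{SVCallSet} of transmission-validated son records.
#' @export
transmissionValidate <- function(callsets, pedigree, minOverlap = 25,
                                 insWindow = 25, reciprocalFraction = 0.5,
                                 label = "FAM") {
    stopifnot(is.list(callsets), !is.null(names(callsets)),
              all(c("son", "sire") %in% names(pedigree)))
    missing <- setdiff(unique(c(pedigree$son, pedigree$sire)),
                       names(callsets))
    if (length(missing)) {
        warning("no call set for sample(s): ",
                paste(missing, collapse = ", "), "; pair(s) skipped")
        keep <- !(pedigree$son %in% missing | pedigree$sire %in% missing)
        pedigree <- pedigree[keep, , drop = FALSE]
    }
    validated <- list()
    for (k in seq_len(nrow(pedigree))) {
        son <- callsets[[pedigree$son[k]]]
        sire <- callsets[[pedigree$sire[k]]]
        if (!length(son) || !length(sire))
            next
        m <- .matchCallSets(son, sire, minOverlap, insWindow)
        if (nrow(m))
            validated[[length(validated) + 1L]] <- svCalls(son)[m$i]
    }
    if (!length(validated))
        return(SVCallSet(GRanges(), label = label))
    gr <- suppressWarnings(do.call(c, unname(validated)))
    mcols(gr)$caller <- label
    ## de-duplicate SV validated through more than one pair
    gr <- sortSeqlevels(gr)
    gr <- gr[order(gr)]
    comp <- .clusterRecords(gr, frac = reciprocalFraction,
                            insWindow = insWindow)
    gr <- gr[!duplicated(comp)]
    SVCallSet(gr, label = label)
}

#' Compare sequence-derived SV with SNP-chip CNV calls
#'
#' SNP arrays resolve only large unbalanced events, so the comparison is
#' restricted to sequence SV longer than \code{minSize} bp of types DEL and
#' DUP.  A sequence SV counts as confirmed when it overlaps a chip CNV of the
#' same type by at least 1 bp.
#'
#' @param seqSet \code{SVCallSet} from sequence data.
#' @param chipSet \code{SVCallSet} of chip CNV (DEL/DUP only; inversions are
#'   an error, as arrays cannot detect balanced events).
#' @param minSize size threshold, bp (default 5000; records must be larger).
#' @return named numeric vector: fraction of large sequence DEL and DUP
#'   confirmed by the chip set (NA when no sequence record of the type passes
#'   the size filter).
#' @export
compareWithChipCnv <- function(seqSet, chipSet, minSize = 5000) {
    stopifnot(is(seqSet, "SVCallSet"), is(chipSet, "SVCallSet"))
    if (any(svType(chipSet) == "INV"))
        stop("chip CNV set contains INV records; arrays cannot detect inversions")
    vapply(c(DEL = "DEL", DUP = "DUP"), function(tp) {
        big <- seqSet[svType(seqSet) == tp & svLength(seqSet) > minSize]
        if (!length(big))
            return(NA_real_)
        chip <- chipSet[svType(chipSet) == tp]
        if (!length(chip))
            return(0)
        mean(countOverlaps(svCalls(big), svCalls(chip)) > 0)
    }, numeric(1))
}
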