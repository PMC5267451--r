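#' Genes overlapped by validated SV
#'
#' A gene is reported when a single SV overlaps it by at least \code{minBp} bp
#' (the per-SV rule; set \code{perSv = FALSE} to sum overlap across SV
#' instead).  An insertion contributes its inserted length when its breakpoint
#' falls inside the gene.  Genes whose whole span lies inside one SV are
#' additionally flagged as completely encompassed.
#'
#' @param genes named \code{GRanges} of gene spans.
#' @param sv an \code{SVCallSet}.
#' @param minBp minimum overlap, bp (default 50).
#' @param perSv apply the threshold per SV (default) rather than to the summed
#'   overlap.
#' @return \code{data.frame} with one row per reported gene: \code{gene},
#'   \code{n_sv}, \code{max_overlap_bp}, \code{svtypes} (comma-separated) and
#'   \code{encompassed}.
#' @export
genesOverlappingSv <- function(genes, sv, minBp = 50, perSv = TRUE) {
    stopifnot(is(genes, "GRanges"), is(sv, "SVCallSet"))
    if (is.null(names(genes)))
        stop("'genes' must be named")
    gr <- svCalls(sv)
    ins <- svType(sv) == "INS"
    rows <- list()
    h <- findOverlaps(genes, gr[!ins])
    if (length(h)) {
        gi <- queryHits(h)
        si <- which(!ins)[subjectHits(h)]
        rows[[1]] <- data.frame(
            gene = gi, sv = si,
            overlap = as.numeric(overlapLength(genes[gi], gr[si])),
            encompassed = start(gr)[si] <= start(genes)[gi] &
                end(gr)[si] >= end(genes)[gi])
    }
    h2 <- findOverlaps(genes, gr[ins])
    if (length(h2)) {
        gi <- queryHits(h2)
        si <- which(ins)[subjectHits(h2)]
        rows[[2]] <- data.frame(
            gene = gi, sv = si,
            overlap = svLength(sv)[si],
            encompassed = FALSE)
    }
    if (!length(rows))
        return(data.frame(gene = character(), n_sv = integer(),
                          max_overlap_bp = numeric(), svtypes = character(),
                          encompassed = logical()))
    hits <- do.call(rbind, rows)
    out <- do.call(rbind, lapply(split(hits, hits$gene), function(d) {
        qual <- if (perSv) d$overlap >= minBp else sum(d$overlap) >= minBp
        if (!any(qual))
            return(NULL)
        dq <- if (perSv) d[d$overlap >= minBp, , drop = FALSE] else d
        data.frame(gene = names(genes)[d$gene[1]],
                   n_sv = nrow(dq),
                   max_overlap_bp = max(d$overlap),
                   svtypes = paste(sort(unique(svType(sv)[dq$sv])),
                                   collapse = ","),
                   encompassed = any(d$encompassed))
    }))
    if (is.null(out))
        return(data.frame(gene = character(), n_sv = integer(),
                          max_overlap_bp = numeric(), svtypes = character(),
                          encompassed = logical()))
    rownames(out) <- NULL
    out[order(out$gene), , drop = FALSE]
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Tests independence of gene-set membership (e.g. conserved vs other genes)
#' and SV status.  No continuity correction is applied; expected counts come
#' from the row and column marginals.
#'
#' @param x 2x2 matrix of observed counts, e.g.
#'   \code{rbind(c(focal_with_sv, other_with_sv),
#'               c(focal_without_sv, other_without_sv))}.
#' @return list with \code{statistic}, \code{p.value}, \code{df} (= 1) and
#'   \code{expected}.
#' @examples
#' chisq2x2(rbind(c(8, 965), c(229, 12555)))$statistic  # 5.0155
#' @export
chisq2x2 <- function(x) {
    x <- as.matrix(x)
    if (!all(dim(x) == c(2L, 2L)))
        stop("'x' must be a 2x2 table")
    if (any(x < 0) || anyNA(x))
        stop("counts must be non-negative")
    if (any(rowSums(x) == 0) || any(colSums(x) == 0))
        stop("zero marginal in contingency table")
    ct <- suppressWarnings(chisq.test(x, correct = FALSE))
    list(statistic = unname(ct$statistic), p.value = ct$p.value,
         df = unname(ct$parameter), expected = ct$expected)
}

#' Proportion of focal and background regions covered by SV
#'
#' The focal proportion is the SV-covered length inside the focal regions over
#' the total focal length; the background proportion is computed on the genome
#' minus the focal and excluded regions.  Insertions occupy no reference span
#' and do not contribute.
#'
#' @param sv an \code{SVCallSet}.
#' @param focal \code{GRanges} of focal regions (e.g. LINE-1 elements).
#' @param exclude optional \code{GRanges} removed from the background (e.g.
#'   exons, assembly gaps).
#' @param genome \code{Seqinfo}, named chromosome-length vector or
#'   \code{GRanges} of whole chromosomes.
#' @return named numeric vector \code{c(focal = , background = )}.
#' @export
regionSvProportion <- function(sv, focal, exclude = NULL, genome) {
    stopifnot(is(sv, "SVCallSet"), is(focal, "GRanges"))
    layout <- .regionLayout(focal, exclude, genome)
    .regionProps(sv, layout)
}

## pre-reduced focal/background layout on the linear axis, shared across sets
.regionLayout <- function(focal, exclude, genome) {
    gg <- .genomeRanges(genome)
    offsets <- .chromOffsets(as.character(seqnames(gg)))
    ggLin <- .reduceLin(.linearize(gg, offsets))
    focalLin <- .reduceLin(.linearize(granges(focal), offsets))
    focalLen <- .linLength(focalLin)
    if (focalLen == 0)
        stop("focal regions have zero total length")
    dropLin <- if (!is.null(exclude) && length(exclude)) {
        ex <- .linearize(granges(exclude), offsets)
        .reduceLin(list(st = c(focalLin$st, ex$st),
                        en = c(focalLin$en, ex$en)))
    } else focalLin
    bgLen <- .linLength(ggLin) - .intersectLin(dropLin, ggLin)
    if (bgLen <= 0)
        stop("background regions have zero total length")
    list(offsets = offsets, gg = ggLin, focal = focalLin,
         focalLen = focalLen, drop = dropLin, bgLen = bgLen)
}

.regionProps <- function(sv, layout) {
    gr <- svCalls(sv)
    gr <- gr[mcols(gr)$svtype != "INS"]
    cov <- .reduceLin(.linearize(gr, layout$offsets))
    covLen <- .intersectLin(cov, layout$gg)
    c(focal = .intersectLin(cov, layout$focal) / layout$focalLen,
      background = (covLen - .intersectLin(cov, layout$drop)) /
          layout$bgLen)
}

#' Paired t-test on focal vs background proportions
#'
#' @param focal,background numeric vectors of paired proportions (one pair per
#'   SV set).
#' @param alternative \code{"greater"} (focal exceeds background; default),
#'   \code{"less"} or \code{"two.sided"}.
#' @return list with \code{statistic}, \code{p.value}, \code{df} and
#'   \code{mean_difference}.
#' @export
pairedTTest <- function(focal, background,
                        alternative = c("greater", "less", "two.sided")) {
    alternative <- match.arg(alternative)
    if (length(focal) != length(background))
        stop("'focal' and 'background' must have equal length")
    if (length(focal) < 2)
        stop("need at least two pairs")
    if (sd(focal - background) == 0)
        stop("degenerate t-test: zero variance of differences")
    tt <- t.test(focal, background, paired = TRUE, alternative = alternative)
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
         df = unname(tt$parameter),
         mean_difference = mean(focal - background))
}

#' Fold change of focal over background proportion
#'
#' @param focal,background proportions.
#' @return \code{focal / background}; NA with a warning when the background
#'   proportion is 0.
#' @export
foldChange <- function(focal, background) {
    out <- ifelse(background > 0, focal / background, NA_real_)
    if (anyNA(out))
        warning("background proportion is 0; fold change undefined")
    out
}

#' Region enrichment analysis across several SV sets
#'
#' Convenience wrapper computing, for each SV set, the focal and background
#' SV-covered proportions and their fold change, followed by a paired t-test
#' across the sets.
#'
#' @param svSets named list of \code{SVCallSet}s.
#' @param focal,exclude,genome see \code{\link{regionSvProportion}}.
#' @param alternative see \code{\link{pairedTTest}}.
#' @return list with \code{proportions} (data.frame: set, focal, background,
#'   fold_change), \code{statistic}, \code{p.value}, \code{df}.
#' @export
regionEnrichment <- function(svSets, focal, exclude = NULL, genome,
                             alternative = c("greater", "less",
                                             "two.sided")) {
    alternative <- match.arg(alternative)
    stopifnot(is.list(svSets), !is.null(names(svSets)))
    layout <- .regionLayout(focal, exclude, genome)
    props <- t(vapply(svSets, function(sv)
        .regionProps(sv, layout), numeric(2)))
    fc <- suppressWarnings(foldChange(props[, "focal"],
                                      props[, "background"]))
    tt <- pairedTTest(props[, "focal"], props[, "background"], alternative)
    list(proportions = data.frame(set = names(svSets),
                                  focal = props[, "focal"],
                                  background = props[, "background"],
                                  fold_change = fc, row.names = NULL),
         statistic = tt$statistic, p.value = tt$p.value, df = tt$df)
}
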