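## Internal matching machinery shared by the consensus, validation and
## benchmark layers.  All matchers are one-to-one and greedy, ordered by
## descending score with ties broken by ascending (chrom, start) of both
## records, which makes the result independent of input record order.

## candidate pairs between two GRanges of SV records.
## score: overlap bp for non-INS (>= minOverlap), insWindow + 1 - |breakpoint
## distance| for INS pairs within the window.
.pairCandidates <- function(grA, grB, minOverlap = 25, insWindow = 25,
                            requireSample = FALSE) {
    empty <- data.frame(i = integer(), j = integer(), score = numeric(),
                        overlap = numeric())
    if (!length(grA) || !length(grB))
        return(empty)
    tA <- mcols(grA)$svtype
    tB <- mcols(grB)$svtype
    out <- list()
    ## reference-span types
    aRef <- which(tA != "INS")
    bRef <- which(tB != "INS")
    if (length(aRef) && length(bRef)) {
        h <- suppressWarnings(
            findOverlaps(grA[aRef], grB[bRef],
                         minoverlap = max(1L, as.integer(minOverlap))))
        if (length(h)) {
            i <- aRef[queryHits(h)]
            j <- bRef[subjectHits(h)]
            keep <- tA[i] == tB[j]
            i <- i[keep]; j <- j[keep]
            ov <- overlapLength(grA[i], grB[j])
            out[[length(out) + 1L]] <-
                data.frame(i = i, j = j, score = as.numeric(ov), overlap = ov)
        }
    }
    ## insertions: breakpoint proximity
    aIns <- which(tA == "INS")
    bIns <- which(tB == "INS")
    if (length(aIns) && length(bIns)) {
        h <- suppressWarnings(
            findOverlaps(grA[aIns], grB[bIns],
                         maxgap = as.integer(insWindow) + 1L))
        if (length(h)) {
            i <- aIns[queryHits(h)]
            j <- bIns[subjectHits(h)]
            d <- abs(start(grA)[i] - start(grB)[j])
            keep <- d <= insWindow
            i <- i[keep]; j <- j[keep]; d <- d[keep]
            out[[length(out) + 1L]] <-
                data.frame(i = i, j = j, score = insWindow + 1 - d,
                           overlap = 0)
        }
    }
    if (!length(out))
        return(empty)
    cand <- do.call(rbind, out)
    if (requireSample) {
        keep <- mcols(grA)$sample[cand$i] == mcols(grB)$sample[cand$j]
        cand <- cand[keep, , drop = FALSE]
    }
    cand
}

## deterministic greedy one-to-one selection over a candidate table
.greedySelect <- function(cand, grA, grB) {
    if (!nrow(cand))
        return(cand)
    ord <- order(-cand$score,
                 as.integer(seqnames(grA))[cand$i], start(grA)[cand$i],
                 as.integer(seqnames(grB))[cand$j], start(grB)[cand$j],
                 cand$i, cand$j)
    cand <- cand[ord, , drop = FALSE]
    usedA <- logical(length(grA))
    usedB <- logical(length(grB))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (!usedA[i] && !usedB[j]) {
            usedA[i] <- TRUE
            usedB[j] <- TRUE
            keep[k] <- TRUE
        }
    }
    cand[keep, , drop = FALSE]
}

## one-to-one matching between two call sets (same-type records only)
.matchCallSets <- function(a, b, minOverlap = 25, insWindow = 25,
                           requireSample = FALSE) {
    grA <- svCalls(a)
    grB <- svCalls(b)
    cand <- .pairCandidates(grA, grB, minOverlap, insWindow, requireSample)
    .greedySelect(cand, grA, grB)
}

## consensus records for matched pairs: intersection span for reference-span
## types; for INS pairs the record of the first set with min'd support.
.consensusRecords <- function(grA, grB, pairs, callerLabel) {
    if (!nrow(pairs)) {
        gr <- grA[0]
        mcols(gr)$caller <- character()
        return(gr)
    }
    ga <- grA[pairs$i]
    gb <- grB[pairs$j]
    ins <- mcols(ga)$svtype == "INS"
    st <- pmax(start(ga), start(gb))
    en <- pmin(end(ga), end(gb))
    st[ins] <- start(ga)[ins]
    en[ins] <- end(ga)[ins]
    gr <- GRanges(seqnames(ga), IRanges(st, en),
                  seqinfo = seqinfo(ga))
    svlen <- as.numeric(en - st + 1L)
    svlen[ins] <- pmin(mcols(ga)$svlen, mcols(gb)$svlen)[ins]
    mcols(gr) <- DataFrame(
        svtype = mcols(ga)$svtype,
        svlen = svlen,
        support = pmin(mcols(ga)$support, mcols(gb)$support),
        sample = mcols(ga)$sample,
        caller = callerLabel,
        genotype = ifelse(mcols(ga)$genotype == mcols(gb)$genotype,
                          mcols(ga)$genotype, "UNKNOWN"))
    gr
}

## connected components of same-type records under >= frac reciprocal overlap
## (INS: breakpoints within insWindow); returns integer component ids.
.clusterRecords <- function(gr, frac = 0.5, insWindow = 25) {
    n <- length(gr)
    if (!n)
        return(integer())
    tp <- mcols(gr)$svtype
    edges <- list()
    ref <- which(tp != "INS")
    if (length(ref) > 1) {
        h <- findOverlaps(gr[ref], drop.self = TRUE, drop.redundant = TRUE)
        if (length(h)) {
            i <- ref[queryHits(h)]
            j <- ref[subjectHits(h)]
            keep <- tp[i] == tp[j]
            i <- i[keep]; j <- j[keep]
            ov <- overlapLength(gr[i], gr[j])
            keep <- ov >= frac * width(gr)[i] & ov >= frac * width(gr)[j]
            edges[[length(edges) + 1L]] <- cbind(i[keep], j[keep])
        }
    }
    ins <- which(tp == "INS")
    if (length(ins) > 1) {
        h <- findOverlaps(gr[ins], maxgap = as.integer(insWindow) + 1L,
                          drop.self = TRUE, drop.redundant = TRUE)
        if (length(h)) {
            i <- ins[queryHits(h)]
            j <- ins[subjectHits(h)]
            keep <- abs(start(gr)[i] - start(gr)[j]) <= insWindow
            edges[[length(edges) + 1L]] <- cbind(i[keep], j[keep])
        }
    }
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    for (e in edges) {
        if (!is.null(e) && nrow(e)) {
            for (k in seq_len(nrow(e))) {
                ri <- find(e[k, 1L])
                rj <- find(e[k, 2L])
                if (ri != rj) parent[ri] <- rj
            }
        }
    }
    vapply(seq_len(n), find, integer(1))
}

## total intersection length of two sets of ranges, each internally reduced
## (no within-set overlap); a single findOverlaps pass, much cheaper than
## GenomicRanges::intersect for repeated calls
.intersectionLength <- function(a, b) {
    if (!length(a) || !length(b))
        return(0)
    h <- suppressWarnings(findOverlaps(a, b))
    if (!length(h))
        return(0)
    q <- queryHits(h)
    s <- subjectHits(h)
    sum(as.numeric(pmin(end(a)[q], end(b)[s]) -
                   pmax(start(a)[q], start(b)[s]) + 1))
}

## ---- linearized interval arithmetic --------------------------------------
## Hot-loop helpers that map (chrom, start, end) onto one numeric axis (one
## large offset per chromosome) so that union/intersection lengths reduce to
## sort/cumsum sweeps; used where thousands of small coverage computations
## would otherwise pay S4 dispatch per call.

.CHROM_STRIDE <- 1e10

.chromOffsets <- function(chroms) {
    structure((seq_along(chroms) - 1) * .CHROM_STRIDE, names = chroms)
}

.linearize <- function(gr, offsets) {
    ch <- as.character(seqnames(gr))
    idx <- match(ch, names(offsets))
    keep <- !is.na(idx)
    list(st = offsets[idx[keep]] + start(gr)[keep],
         en = offsets[idx[keep]] + end(gr)[keep])
}

## union of closed intervals on the linear axis
.reduceLin <- function(lin) {
    st <- lin$st
    en <- lin$en
    n <- length(st)
    if (n < 2)
        return(lin)
    o <- order(st)
    st <- st[o]
    en <- en[o]
    cm <- cummax(en)
    new <- c(TRUE, st[-1] > cm[-n] + 1)
    last <- c(which(new)[-1] - 1L, n)
    list(st = st[new], en = cm[last])
}

.linLength <- function(lin) sum(lin$en - lin$st + 1)

## intersection length of two reduced linear interval sets (event sweep)
.intersectLin <- function(a, b) {
    nA <- length(a$st)
    nB <- length(b$st)
    if (!nA || !nB)
        return(0)
    ev <- c(a$st, a$en + 1, b$st, b$en + 1)
    dA <- c(rep(1, nA), rep(-1, nA), rep(0, 2 * nB))
    dB <- c(rep(0, 2 * nA), rep(1, nB), rep(-1, nB))
    o <- order(ev)
    ev <- ev[o]
    cA <- cumsum(dA[o])
    cB <- cumsum(dB[o])
    k <- length(ev)
    sum((ev[-1] - ev[-k])[cA[-k] > 0 & cB[-k] > 0])
}

## normalise a genome given as Seqinfo or named lengths into a GRanges of
## whole chromosomes
.genomeRanges <- function(genome) {
    if (is(genome, "Seqinfo")) {
        GRanges(seqnames(genome), IRanges(1, seqlengths(genome)),
                seqinfo = genome)
    } else if (is.numeric(genome) && !is.null(names(genome))) {
        si <- Seqinfo(names(genome), genome)
        GRanges(names(genome), IRanges(1, unname(genome)), seqinfo = si)
    } else if (is(genome, "GRanges")) {
        genome
    } else {
        stop("'genome' must be a Seqinfo, a named length vector or a GRanges")
    }
}

.localSeed <- function(seed) {
    if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
}
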