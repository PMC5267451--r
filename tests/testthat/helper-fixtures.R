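library(GenomicRanges)

## Build an SVCallSet from parallel vectors (1-based closed coordinates).
cs <- function(chrom, start, end, svtype, svlen = NULL, support = 10L,
               sample = "s1", caller = "test", genotype = "UNKNOWN",
               label = "test", seqinfo = NULL) {
    gr <- GRanges(chrom, IRanges(start, end))
    if (!is.null(seqinfo)) seqinfo(gr) <- seqinfo
    SVCallSet(gr, label = label, svtype = svtype, svlen = svlen,
              support = support, sample = sample, caller = caller,
              genotype = genotype)
}

## Independent per-base oracle for union covered length: mark every covered
## base of every chromosome in a logical mask and count.  Only valid for
## small genomes; insertions contribute their inserted length.
maskCoveredLength <- function(x, chromLengths) {
    gr <- svCalls(x)
    ins <- svType(x) == "INS"
    total <- 0
    for (chr in names(chromLengths)) {
        mask <- logical(chromLengths[[chr]])
        sel <- which(!ins & as.character(seqnames(gr)) == chr)
        for (i in sel)
            mask[start(gr)[i]:end(gr)[i]] <- TRUE
        total <- total + sum(mask)
    }
    total + sum(svLength(x)[ins])
}

## Textbook chi-square from marginals (independent of stats::chisq.test).
chisqOracle <- function(x) {
    E <- outer(rowSums(x), colSums(x)) / sum(x)
    sum((x - E)^2 / E)
}

## Random SVCallSet on a toy genome (no placement constraints).
randomCallSet <- function(n, chromLengths, types = c("DEL", "INV", "DUP"),
                          sizeRange = c(30, 500), sample = "s1",
                          label = "rand") {
    chr <- sample(names(chromLengths), n, replace = TRUE)
    size <- round(exp(runif(n, log(sizeRange[1]), log(sizeRange[2]))))
    st <- floor(runif(n, 1, unlist(chromLengths)[chr] - size))
    cs(chr, st, st + size - 1, sample(types, n, replace = TRUE),
       sample = sample, label = label)
}

toyGenome <- function() {
    simulateGenome(nChrom = 2, chromLength = 2e6, repeatFraction = 0.1,
                   exonFraction = 0.02, gapCount = 2, nGenes = 40,
                   seed = 99)
}
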