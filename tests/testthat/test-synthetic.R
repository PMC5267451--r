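test_that("generators are reproducible under a fixed seed", {
    g1 <- simulateGenome(seed = 7)
    g2 <- simulateGenome(seed = 7)
    expect_identical(g1, g2)
    sc <- scenarioConfig(nSvPerType = c(DEL = 20L, INV = 20L, DUP = 20L))
    t1 <- simulateTruthSv(g1, sc, seed = 8)
    t2 <- simulateTruthSv(g2, sc, seed = 8)
    expect_identical(svCalls(t1), svCalls(t2))
    pr <- callerProfile("split_read_like")
    c1 <- emulateCaller(t1, pr, sc, genome = g1, seed = 9)
    c2 <- emulateCaller(t2, pr, sc, genome = g2, seed = 9)
    expect_identical(svCalls(c1), svCalls(c2))
})

test_that("simulated genomes hit the requested annotation structure", {
    g <- simulateGenome(nChrom = 2, chromLength = 1e6,
                        repeatFraction = 0.2, gapCount = 3, nGenes = 50,
                        seed = 12)
    expect_length(g$gaps, 3)
    expect_length(g$genes, 50)
    repFrac <- sum(width(g$repeats)) / sum(seqlengths(g$seqinfo))
    expect_lt(abs(repFrac - 0.2), 0.02)
    ## tracks are internally non-overlapping
    expect_equal(length(reduce(g$repeats)), length(g$repeats))
    expect_true(sum(mcols(g$genes)$conserved) > 0)
    expect_true(sum(mcols(g$genes)$family) > 0)
    expect_error(simulateGenome(repeatFraction = 0.7, exonFraction = 0.4),
                 "sum to more than 1")
})

test_that("truth panels respect scenario counts, zygosity and placement", {
    g <- toyGenome()
    truth <- simulateTruthSv(g, scenarioConfig(), seed = 3)
    expect_equal(unname(table(svType(truth))[c("DEL", "INV", "DUP")]),
                 rep(100L, 3), ignore_attr = TRUE)
    expect_true(all(svGenotype(truth) == "HOM"))
    ## truth SV never overlap each other or assembly gaps
    expect_equal(length(reduce(granges(svCalls(truth)))), length(truth))
    expect_equal(sum(countOverlaps(svCalls(truth), g$gaps)), 0)
    ## HET scenario: everything heterozygous at halved per-haplotype coverage
    het <- simulateTruthSv(g, scenarioConfig(preset = "HET"), seed = 4)
    expect_true(all(svGenotype(het) == "HET"))
    ## repetitive scenario: every SV is anchored in a repeat region
    rep1 <- simulateTruthSv(g, scenarioConfig(
        preset = "REP", nSvPerType = c(DEL = 30L, INV = 30L, DUP = 30L),
        sizeRange = c(100, 1000)), seed = 5)
    expect_true(all(countOverlaps(svCalls(rep1), g$repeats) > 0))
})

test_that("a perfect profile reproduces the truth panel exactly", {
    g <- toyGenome()
    truth <- simulateTruthSv(g, scenarioConfig(), seed = 14)
    calls <- emulateCaller(truth, callerProfile("perfect"),
                           scenarioConfig(), genome = g, seed = 15)
    expect_identical(granges(svCalls(calls)), granges(svCalls(truth)))
    expect_identical(svLength(calls), svLength(truth))
})

test_that("population genotypes follow allele frequency and Mendelian rules", {
    g <- toyGenome()
    panel <- simulateTruthSv(g, scenarioConfig(
        nSvPerType = c(DEL = 20L, DUP = 20L), sizeRange = c(100, 1000)),
        seed = 21)
    samples <- c("sire1", paste0("son", 1:6))
    ped <- data.frame(son = paste0("son", 1:6), sire = "sire1")
    ## allele frequency 1: every sample carries every SV homozygously
    pop <- simulatePopulation(g, panel, rep(1, length(panel)), samples, ped,
                              profiles = list(p = callerProfile("perfect")),
                              seed = 22)
    expect_true(all(pop$genotypes == 2L))
    ## HOM sire transmits to every son even at low population frequency
    pop2 <- simulatePopulation(g, panel, rep(0.05, length(panel)), samples,
                               ped,
                               profiles = list(p = callerProfile("perfect")),
                               seed = 23)
    sireHom <- pop2$genotypes["sire1", ] == 2L
    for (s in paste0("son", 1:6))
        expect_true(all(pop2$genotypes[s, sireHom] >= 1L))
    ## pedigree cycles are rejected
    bad <- data.frame(son = c("a", "b"), sire = c("b", "a"))
    expect_error(simulatePopulation(g, panel, rep(0.5, length(panel)),
                                    c("a", "b"), bad, seed = 24),
                 "cycle")
})

test_that("heterozygous sires transmit their allele half of the time", {
    g <- toyGenome()
    panel <- simulateTruthSv(g, scenarioConfig(
        nSvPerType = c(DEL = 10L), sizeRange = c(200, 1000)), seed = 31)
    nSons <- 400
    samples <- c("sire1", paste0("s", seq_len(nSons)))
    ped <- data.frame(son = paste0("s", seq_len(nSons)), sire = "sire1")
    pop <- simulatePopulation(g, panel, rep(0.5, length(panel)), samples,
                              ped,
                              profiles = list(p = callerProfile("perfect")),
                              seed = 32)
    het <- pop$genotypes["sire1", ] == 1L
    expect_true(any(het))
    ## given a HET sire, a son carries the SV unless both the sire allele
    ## (probability 1/2) and the population allele (frequency 1/2) miss:
    ## 1 - 1/2 * 1/2 = 3/4
    rate <- mean(pop$genotypes[paste0("s", seq_len(nSons)), het] >= 1L)
    se <- sqrt(0.75 * 0.25 / (nSons * sum(het)))
    expect_lt(abs(rate - 0.75), 4 * se + 0.01)
})

test_that("twice-sequenced emulation obeys the insert-size eligibility split", {
    g <- toyGenome()
    truth <- simulateTruthSv(g, scenarioConfig(
        nSvPerType = c(DEL = 20L, INV = 20L), sizeRange = c(100, 1000)),
        seed = 41)
    tw <- simulateTwiceSequenced(truth, callerProfile("perfect"),
                                 nIndividuals = 28, nIneligible = 7,
                                 genome = g, seed = 42)
    meta <- attr(tw, "meta")
    expect_equal(sum(meta$merge_eligible), 21)
    expect_equal(mergeEligible(meta), meta$merge_eligible)
    ## perfect profile: both replicates and the merged set reproduce truth
    expect_identical(granges(svCalls(tw[[1]]$rep1)),
                     granges(svCalls(truth)))
    expect_identical(granges(svCalls(tw[[1]]$merged)),
                     granges(svCalls(truth)))
})
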