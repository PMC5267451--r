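test_that("twice-sequenced validation keeps only replicate-supported calls", {
    set.seed(21)
    x <- randomCallSet(100, list(chr1 = 1e6), sizeRange = c(50, 500))
    same <- twiceSequencedValidate(x, x)
    expect_length(same, 100)
    expect_identical(granges(svCalls(same)), granges(svCalls(x)))
    ## disjoint replicates validate nothing
    y <- cs("chr2", 1, 100, "DEL")
    expect_length(twiceSequencedValidate(x, y), 0)
})

test_that("independent replicate detection yields the product rate", {
    g <- toyGenome()
    sc <- scenarioConfig(nSvPerType = c(DEL = 40L, INV = 40L, DUP = 40L),
                         sizeRange = c(100, 2000))
    truth <- simulateTruthSv(g, sc, seed = 31)
    prof <- callerProfile(detection = c(DEL = 0.8, INS = 0.8, INV = 0.8,
                                        DUP = 0.8),
                          fpPerMb = 0, jitterSd = 2, sizeErrorSd = 0.01)
    rate <- replicate(50, {
        r1 <- emulateCaller(truth, prof, sc, genome = g)
        r2 <- emulateCaller(truth, prof, sc, genome = g)
        length(twiceSequencedValidate(r1, r2)) / length(truth)
    })
    ## P(both replicates detect) = 0.8^2 = 0.64; 3 sigma over 50x120 trials
    se <- sqrt(0.64 * 0.36 / (50 * length(truth)))
    expect_lt(abs(mean(rate) - 0.64), 3 * se + 0.01)
})

test_that("merge/overlap concordance follows the SHARE formula", {
    set.seed(41)
    m <- randomCallSet(100, list(chr1 = 1e6))
    o <- randomCallSet(200, list(chr1 = 1e6))
    r <- mergeOverlapConcordance(m, o)
    expect_equal(r$overlap_percent,
                 r$shared_count / min(100, 200) * 100)
    ## identical sets share everything: bound attained
    r2 <- mergeOverlapConcordance(m, m)
    expect_equal(r2$overlap_percent, 100)
    ## symmetric in the labelling of the two methods
    r3 <- mergeOverlapConcordance(o, m)
    expect_equal(r3$overlap_percent, r$overlap_percent)
    expect_error(mergeOverlapConcordance(SVCallSet(GRanges()),
                                         SVCallSet(GRanges())), "empty")
})

test_that("merged-evidence concordance reflects the pooled detection rate", {
    ## with per-run detection p, the pooled-evidence set detects
    ## 1 - (1 - p)^2 of the truth; the concordance with the replicate-overlap
    ## set (yield p^2, always the smaller set) then converges to that rate:
    ## p = 0.49 gives about 74%
    g <- toyGenome()
    truth <- simulateTruthSv(g, scenarioConfig(
        nSvPerType = c(DEL = 40L, DUP = 40L), sizeRange = c(100, 2000)),
        seed = 61)
    prof <- callerProfile(detection = c(DEL = .49, INS = .49, INV = .49,
                                        DUP = .49),
                          fpPerMb = 0, jitterSd = 2, sizeErrorSd = 0.01,
                          repeatPenalty = 0, baseErrorSlope = 0,
                          snpInSvSlope = 0)
    tw <- simulateTwiceSequenced(truth, prof, nIndividuals = 21,
                                 nIneligible = 0, genome = g, seed = 62)
    pct <- vapply(tw, function(ind) {
        ov <- twiceSequencedValidate(ind$rep1, ind$rep2)
        if (!length(ov) || !length(ind$merged))
            return(NA_real_)
        mergeOverlapConcordance(ind$merged, ov)$overlap_percent
    }, numeric(1))
    expect_lt(abs(mean(pct, na.rm = TRUE) - 74), 6)
})

test_that("transmission validation requires a matching sire record", {
    son <- cs("chr1", c(100, 5000), c(400, 5400), c("DEL", "DUP"),
              sample = "son1")
    sire <- cs("chr1", 110, 410, "DEL", sample = "sire1")
    ped <- data.frame(son = "son1", sire = "sire1")
    v <- transmissionValidate(list(son1 = son, sire1 = sire), ped)
    expect_length(v, 1)
    expect_equal(svType(v), "DEL")            # son-only DUP not validated
    expect_equal(unique(svCaller(v)), "FAM")
    ## missing sample: pair skipped with a warning
    expect_warning(
        v2 <- transmissionValidate(list(son1 = son), ped), "no call set")
    expect_length(v2, 0)
    ## the same SV validated through two pairs is reported once
    son2 <- cs("chr1", 102, 402, "DEL", sample = "son2")
    ped2 <- data.frame(son = c("son1", "son2"), sire = c("sire1", "sire1"))
    v3 <- transmissionValidate(list(son1 = son, son2 = son2, sire1 = sire),
                               ped2)
    expect_length(v3, 1)
})

test_that("transmission output is always a subset of son calls", {
    g <- toyGenome()
    sc <- scenarioConfig(nSvPerType = c(DEL = 30L, DUP = 30L),
                         sizeRange = c(100, 1000))
    panel <- simulateTruthSv(g, sc, seed = 55)
    pop <- simulatePopulation(
        g, panel, alleleFreq = rep(0.4, length(panel)),
        samples = c("sire1", "son1", "son2"),
        pedigree = data.frame(son = c("son1", "son2"),
                              sire = c("sire1", "sire1")),
        profiles = list(pem = callerProfile("paired_end_like", fpPerMb = 0)),
        scenario = sc, seed = 56)
    calls <- pop$calls$pem
    v <- transmissionValidate(calls, data.frame(
        son = c("son1", "son2"), sire = c("sire1", "sire1")))
    sons <- c(svCalls(calls$son1), svCalls(calls$son2))
    expect_true(all(countOverlaps(svCalls(v), sons, type = "equal") > 0))
})

test_that("chip comparison restricts to large unbalanced events", {
    seqSet <- cs("chr1", c(1000, 20000, 50000), c(4999, 30000, 70000),
                 c("DEL", "DEL", "DUP"))
    chip <- cs("chr1", c(19000, 100000), c(31000, 120000), c("DEL", "DUP"))
    r <- compareWithChipCnv(seqSet, chip)
    ## the 4 kb DEL is excluded; the 10 kb DEL matches; the DUP does not
    expect_equal(unname(r["DEL"]), 1.0)
    expect_equal(unname(r["DUP"]), 0.0)
    ## empty chip set: confirmed fraction 0
    r2 <- compareWithChipCnv(seqSet, SVCallSet(GRanges()))
    expect_equal(unname(r2["DEL"]), 0)
    expect_error(compareWithChipCnv(seqSet, cs("chr1", 1, 6000, "INV")),
                 "INV")
})
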