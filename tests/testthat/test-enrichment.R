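test_that("gene overlap reporting uses the per-SV 50 bp rule", {
    genes <- GRanges("chr1", IRanges(c(1000, 5000), c(1999, 5999)))
    names(genes) <- c("geneA", "geneB")
    ## 60 bp overlap reported; 49 bp not
    expect_equal(genesOverlappingSv(
        genes, cs("chr1", 1940, 2100, "DEL"))$gene, "geneA")
    expect_equal(nrow(genesOverlappingSv(
        genes, cs("chr1", 1951, 2100, "DEL"))), 0)
    ## containment flag
    r <- genesOverlappingSv(genes, cs("chr1", 900, 2100, "DEL"))
    expect_true(r$encompassed[r$gene == "geneA"])
    ## per-SV rule: two 30 bp overlaps do not qualify unless summed
    two <- cs("chr1", c(1001, 1971), c(1030, 2000), c("DEL", "DEL"))
    expect_equal(nrow(genesOverlappingSv(genes, two)), 0)
    expect_equal(genesOverlappingSv(genes, two, perSv = FALSE)$gene, "geneA")
    ## an insertion inside a gene contributes its inserted length
    insCall <- cs("chr1", 5500, 5500, "INS", svlen = 80)
    expect_equal(genesOverlappingSv(genes, insCall)$gene, "geneB")
})

test_that("2x2 chi-square reproduces the textbook marginals computation", {
    expect_equal(chisq2x2(rbind(c(5, 5), c(5, 5)))$statistic, 0)
    expect_error(chisq2x2(rbind(c(0, 0), c(5, 5))), "marginal")
    expect_error(chisq2x2(matrix(1, 3, 3)), "2x2")
    set.seed(13)
    for (k in 1:200) {
        tab <- matrix(rpois(4, 50) + 1, 2, 2)
        r <- chisq2x2(tab)
        expect_equal(r$statistic, chisqOracle(tab), tolerance = 1e-9)
        expect_equal(r$df, 1)
    }
})

test_that("region SV proportions are coverage ratios over focal and background", {
    genome <- c(chr1 = 10000)
    focal <- GRanges("chr1", IRanges(1001, 3000))       # 2 kb
    sv <- cs("chr1", 1001, 2000, "DEL")                 # covers half of focal
    p <- regionSvProportion(sv, focal, genome = genome)
    expect_equal(unname(p["focal"]), 0.5)
    expect_equal(unname(p["background"]), 0)
    ## no SV at all
    p0 <- regionSvProportion(SVCallSet(GRanges()), focal, genome = genome)
    expect_equal(unname(p0), c(0, 0))
    ## excluded regions are removed from the background universe
    sv2 <- cs("chr1", c(1001, 4001), c(2000, 4800), c("DEL", "DEL"))
    excl <- GRanges("chr1", IRanges(4001, 5000))
    p2 <- regionSvProportion(sv2, focal, exclude = excl, genome = genome)
    expect_equal(unname(p2["background"]), 0)
    expect_error(regionSvProportion(sv, GRanges(), genome = genome),
                 "zero total length")
})

test_that("paired t-test and fold change behave at the edges", {
    expect_error(pairedTTest(c(1, 2, 3), c(0, 1, 2)), "degenerate")
    expect_error(pairedTTest(1, 2), "two pairs")
    r <- pairedTTest(c(0.03, 0.045, 0.05), c(0.01, 0.02, 0.03))
    expect_equal(r$statistic, 13.0, tolerance = 1e-8)
    expect_equal(foldChange(0.4, 0.2), 2)
    expect_equal(foldChange(0, 0.2), 0)
    expect_warning(fc <- foldChange(0.1, 0), "undefined")
    expect_true(is.na(fc))
})

test_that("random SV placement gives fold change near 1", {
    genome <- c(chr1 = 1e5, chr2 = 1e5)
    set.seed(29)
    focal <- GRanges(rep(c("chr1", "chr2"), each = 10),
                     IRanges(rep(seq(1, 9e4, length.out = 10), 2),
                             width = 3000))
    props <- replicate(200, {
        sv <- randomCallSet(60, as.list(genome), types = "DEL",
                            sizeRange = c(100, 500))
        regionSvProportion(sv, focal, genome = genome)
    })
    fc <- mean(props["focal", ]) / mean(props["background", ])
    expect_lt(abs(fc - 1), 0.1)
})

test_that("regionEnrichment summarises proportions and tests across sets", {
    genome <- c(chr1 = 5e4)
    focal <- GRanges("chr1", IRanges(seq(1, 4e4, by = 5000), width = 1000))
    set.seed(31)
    sets <- lapply(1:5, function(i)
        randomCallSet(40, list(chr1 = 5e4), types = "DEL",
                      sizeRange = c(50, 300)))
    names(sets) <- paste0("set", 1:5)
    r <- regionEnrichment(sets, focal, genome = genome)
    expect_equal(nrow(r$proportions), 5)
    expect_true(r$p.value > 0 && r$p.value <= 1)
    expect_equal(r$proportions$fold_change,
                 r$proportions$focal / r$proportions$background)
})
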