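gaps <- GRanges("chr1", IRanges(5000, 6000))

test_that("raw-call filtering applies support, gap, cap and recurrence rules", {
    x <- cs("chr1",
            start  = c(100, 100, 5500, 2000, 2000, 8000, 8000),
            end    = c(300, 305, 5600, 2400, 2410, 8500, 8520),
            svtype = c("DEL", "DEL", "DEL", "DUP", "DUP", "INV", "INV"),
            support = c(3L, 10L, 10L, 25L, 25L, 8L, 9L),
            sample = c("s1", "s2", "s1", "s1", "s2", "s1", "s2"))
    ## support < 4 removed even though its partner record remains
    f1 <- filterRawCalls(x, gaps = gaps, minSupport = 4, minIndividuals = 1)
    expect_false(any(svSupport(f1) < 4))
    ## gap-spanning record removed
    expect_false(any(countOverlaps(svCalls(f1), gaps) > 0))
    ## recurrence: the surviving lone DEL (s2) has no 50%-reciprocal partner
    f2 <- filterRawCalls(x, gaps = gaps, minSupport = 4, minIndividuals = 2)
    expect_setequal(unique(svType(f2)), c("DUP", "INV"))
    expect_length(f2, 4)
    ## idempotent
    f3 <- filterRawCalls(f2, gaps = gaps, minSupport = 4, minIndividuals = 2)
    expect_identical(svCalls(f3), svCalls(f2))
})

test_that("maximum-support cap is per type and coverage scaled", {
    x <- cs("chr1", c(100, 1000, 3000), c(300, 1300, 3300),
            c("DEL", "DUP", "DEL"), support = c(25L, 25L, 15L),
            sample = "s1")
    cov <- c(s1 = 10)
    ## caps: DEL 2x10=20 (25 removed, 15 kept), DUP 4x10=40 (25 kept)
    f <- filterRawCalls(x, minSupport = 4, minIndividuals = 1,
                        coverage = cov, applyMaxSupport = TRUE)
    expect_equal(sort(svSupport(f)), c(15L, 25L))
    expect_setequal(svType(f), c("DEL", "DUP"))
    expect_error(filterRawCalls(x, minSupport = 4, minIndividuals = 1,
                                applyMaxSupport = TRUE),
                 "missing coverage")
})

test_that("dual-caller intersection needs >= 25 bp same-type same-sample overlap", {
    a <- cs("chr1", c(100, 400, 900), c(200, 600, 1000),
            c("DEL", "DEL", "DEL"), support = c(10L, 8L, 6L))
    b <- cs("chr1", c(170, 580, 900), c(260, 780, 1000),
            c("DEL", "DEL", "DUP"), support = c(7L, 9L, 6L))
    cons <- intersectCallers(a, b)
    ## overlap 31 bp passes; overlap 21 bp fails; type mismatch fails
    expect_length(cons, 1)
    expect_equal(start(svCalls(cons)), 170)
    expect_equal(end(svCalls(cons)), 200)
    expect_equal(svSupport(cons), 7L)
    expect_equal(unique(svCaller(cons)), "consensus")
    ## records from different samples never pair
    b2 <- cs("chr1", 100, 200, "DEL", sample = "other")
    expect_length(intersectCallers(a, b2), 0)
})

test_that("intersection is order-invariant and one-to-one", {
    set.seed(5)
    lens <- list(chr1 = 1e5, chr2 = 1e5)
    a <- randomCallSet(120, lens, sizeRange = c(50, 800))
    b <- randomCallSet(120, lens, sizeRange = c(50, 800))
    cons <- intersectCallers(a, b)
    shuf <- function(x) x[sample(length(x))]
    cons2 <- intersectCallers(shuf(a), shuf(b))
    expect_identical(svCalls(cons), svCalls(cons2))
    ## one-to-one: consensus can never exceed either input per type
    for (tp in c("DEL", "INV", "DUP")) {
        expect_lte(sum(svType(cons) == tp),
                   min(sum(svType(a) == tp), sum(svType(b) == tp)))
        expect_lte(unionCoveredLength(cons[svType(cons) == tp]),
                   min(unionCoveredLength(a[svType(a) == tp]),
                       unionCoveredLength(b[svType(b) == tp])))
    }
})

test_that("population summary counts and coverage match the per-base oracle", {
    expect_equal(populationSummary(SVCallSet(GRanges()))$covered_bp,
                 rep(0, 5))
    set.seed(11)
    lens <- c(chr1 = 2e4, chr2 = 2e4)
    x <- randomCallSet(10, as.list(lens), sizeRange = c(100, 2000))
    ps <- populationSummary(x)
    for (tp in c("DEL", "INV", "DUP"))
        expect_equal(ps$covered_bp[ps$svtype == tp],
                     maskCoveredLength(x[svType(x) == tp], lens))
    expect_equal(ps$covered_bp[ps$svtype == "total"],
                 sum(ps$covered_bp[ps$svtype != "total"]))
    expect_equal(ps$n[ps$svtype == "total"], 10)
})

test_that("shared coverage reports intersection length and fractions", {
    a <- cs("chr1", c(100, 1000), c(499, 1399), c("DEL", "DUP"))
    b <- cs("chr1", c(300, 5000), c(699, 5399), c("DEL", "DUP"))
    sh <- sharedCoverage(a, b)
    expect_equal(unname(sh$by_type["DEL"]), 200)
    expect_equal(unname(sh$by_type["DUP"]), 0)
    expect_equal(sh$fraction_of_a, 200 / 800)
    ## identity and disjoint extremes
    expect_equal(sharedCoverage(a, a)$fraction_of_a, 1.0)
    expect_equal(sharedCoverage(a, cs("chr2", 1, 100, "DEL"))$shared_bp, 0)
})

test_that("expected-overlap t-test matches a hand-computed paired t", {
    obs <- c(c1 = 0.030, c2 = 0.045, c3 = 0.050)
    covA <- c(c1 = 0.10, c2 = 0.20, c3 = 0.30)
    covB <- c(c1 = 0.1, c2 = 0.1, c3 = 0.1)
    r <- expectedOverlapTest(covA, covB, obs)
    expect_equal(unname(r$expected), c(0.010, 0.020, 0.030))
    expect_equal(r$statistic, 13.0, tolerance = 1e-8)
    expect_equal(r$p.value, 0.002932, tolerance = 1e-3)
    expect_error(expectedOverlapTest(covA, covB, covA * covB + 0.01),
                 "degenerate")
    expect_error(expectedOverlapTest(covA, covB[1:2], obs), "chromosomes")
})
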