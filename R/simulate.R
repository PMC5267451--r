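#' Simulation scenario configuration
#'
#' Bundles the knobs describing one simulation scenario: how many SV of each
#' type to plant, their zygosity, the sequencing coverage and insert-size
#' model, the base-calling error rate, the fraction of SNPs inside SV, and the
#' fraction of SV placed inside repetitive regions.  Presets mirror the four
#' named scenarios commonly contrasted: all-homozygous (\code{"HOM"}),
#' all-heterozygous (\code{"HET"}, coverage 5 per haplotype), all SV in
#' repeats (\code{"REP"}) and the mixed realistic case (\code{"MIX"}:
#' heterozygous, SNP fraction 0.01 in SV, genome-wide SNP rate 0.008, half of
#' the SV in repeats).
#'
#' @param preset optional preset name: \code{"HOM"}, \code{"HET"},
#'   \code{"REP"}, \code{"MIX"}.
#' @param nSvPerType named integer vector of truth SV counts (default 100
#'   each of DEL, INV, DUP; insertions are supported but not part of the
#'   standard scenarios).
#' @param zygosity \code{"HOM"}, \code{"HET"} or \code{"mixed"}.
#' @param coverage mean fold sequence coverage (per haplotype for HET).
#' @param insertSizeMean,insertSizeSd insert-size model, bp.
#' @param baseErrorRate per-base call error rate (scenario range
#'   0.001-0.025).
#' @param snpInSvFraction fraction of SNPs inside SV regions (0-0.25).
#' @param snpRate genome-wide per-locus SNP rate.
#' @param indelRate genome-wide small-indel rate.
#' @param repetitiveSvFraction fraction of truth SV placed inside repeat
#'   regions (0, 0.5 or 1 in the standard scenarios).
#' @param sizeRange truth SV length range, bp; sizes are drawn log-uniformly.
#' @return a \code{ScenarioConfig} list.
#' @export
scenarioConfig <- function(preset = NULL,
                           nSvPerType = c(DEL = 100L, INV = 100L, DUP = 100L),
                           zygosity = c("HOM", "HET", "mixed"),
                           coverage = 10, insertSizeMean = 500,
                           insertSizeSd = 50, baseErrorRate = 0.01,
                           snpInSvFraction = 0, snpRate = 0.01,
                           indelRate = 0.01, repetitiveSvFraction = 0,
                           sizeRange = c(100, 10000)) {
    zygosity <- match.arg(zygosity)
    if (!is.null(preset)) {
        preset <- match.arg(preset, c("HOM", "HET", "REP", "MIX"))
        if (preset == "HET") {
            zygosity <- "HET"
            coverage <- 5
        } else if (preset == "REP") {
            repetitiveSvFraction <- 1
        } else if (preset == "MIX") {
            zygosity <- "HET"
            coverage <- 5
            snpInSvFraction <- 0.01
            snpRate <- 0.008
            repetitiveSvFraction <- 0.5
        }
    }
    rates <- c(baseErrorRate = baseErrorRate,
               snpInSvFraction = snpInSvFraction, snpRate = snpRate,
               indelRate = indelRate,
               repetitiveSvFraction = repetitiveSvFraction)
    if (any(rates < 0 | rates > 1))
        stop("rates must lie in [0, 1]")
    if (any(nSvPerType <= 0) || is.null(names(nSvPerType)))
        stop("'nSvPerType' must be a named vector of positive counts")
    if (!all(names(nSvPerType) %in% .SV_TYPES))
        stop("unknown SV type in 'nSvPerType'")
    if (coverage <= 0 || insertSizeSd < 0)
        stop("'coverage' must be positive and 'insertSizeSd' non-negative")
    if (length(sizeRange) != 2 || any(sizeRange < 1) ||
        sizeRange[1] > sizeRange[2])
        stop("'sizeRange' must be an increasing pair of lengths >= 1")
    structure(list(nSvPerType = nSvPerType, zygosity = zygosity,
                   coverage = coverage, insertSizeMean = insertSizeMean,
                   insertSizeSd = insertSizeSd,
                   baseErrorRate = baseErrorRate,
                   snpInSvFraction = snpInSvFraction, snpRate = snpRate,
                   indelRate = indelRate,
                   repetitiveSvFraction = repetitiveSvFraction,
                   sizeRange = sizeRange),
              class = "ScenarioConfig")
}

#' Emulated caller detection profile
#'
#' Parameterises the call-level emulation of an SV caller: per-type detection
#' probability for homozygous SV, additive detection penalties for
#' heterozygous SV, breakpoint jitter, relative size error, false-positive
#' density, a detection penalty inside repeat regions, and additive penalty
#' slopes mapping the scenario's base-error and SNP-in-SV rates to detection
#' loss (documented in the package vignette).
#'
#' Two presets capture the complementary behaviour of the two caller
#' strategies: a paired-end-mapping style caller (\code{"paired_end_like"}:
#' high inversion sensitivity, nearly zygosity-independent) and a split-read
#' style caller (\code{"split_read_like"}: lower inversion sensitivity and a
#' marked heterozygote deficit, notably -0.35 for deletions, -0.085 for
#' inversions and -0.0515 for duplications).
#'
#' @param preset optional preset: \code{"paired_end_like"},
#'   \code{"split_read_like"}, \code{"perfect"}.
#' @param name caller id recorded on emitted records.
#' @param detection named per-type detection probability for HOM SV.
#' @param hetPenalty named per-type additive penalty for HET SV.
#' @param fpPerMb expected false-positive calls per Mb of genome.
#' @param jitterSd breakpoint jitter standard deviation, bp.
#' @param sizeErrorSd relative size error standard deviation.
#' @param repeatPenalty additive detection penalty inside repeat regions.
#' @param baseErrorSlope additive detection penalty per unit of base error
#'   above the 0.01 reference rate (scaled by (rate - 0.01) / 0.01).
#' @param snpInSvSlope additive detection penalty per unit of SNP-in-SV
#'   fraction.
#' @param supportFactor mean supporting reads per fold of coverage.
#' @return a \code{CallerProfile} list.
#' @export
callerProfile <- function(preset = NULL, name = NULL,
                          detection = c(DEL = 0.80, INS = 0.80, INV = 0.87,
                                        DUP = 0.80),
                          hetPenalty = c(DEL = 0, INS = 0, INV = 0, DUP = 0),
                          fpPerMb = 1, jitterSd = 10, sizeErrorSd = 0.05,
                          repeatPenalty = 0.1, baseErrorSlope = 0.02,
                          snpInSvSlope = 0.2, supportFactor = 1) {
    if (!is.null(preset)) {
        preset <- match.arg(preset, c("paired_end_like", "split_read_like",
                                      "perfect"))
        if (preset == "paired_end_like") {
            detection <- c(DEL = 0.80, INS = 0.80, INV = 0.87, DUP = 0.80)
            hetPenalty <- c(DEL = 0, INS = 0, INV = 0, DUP = 0)
        } else if (preset == "split_read_like") {
            detection <- c(DEL = 0.80, INS = 0.80, INV = 0.58, DUP = 0.80)
            hetPenalty <- c(DEL = 0.35, INS = 0.05, INV = 0.085,
                            DUP = 0.0515)
        } else {
            detection <- c(DEL = 1, INS = 1, INV = 1, DUP = 1)
            hetPenalty <- c(DEL = 0, INS = 0, INV = 0, DUP = 0)
            fpPerMb <- 0
            jitterSd <- 0
            sizeErrorSd <- 0
            repeatPenalty <- 0
            baseErrorSlope <- 0
            snpInSvSlope <- 0
        }
        if (is.null(name))
            name <- preset
    }
    if (is.null(name))
        name <- "emulated"
    detection <- detection[.SV_TYPES]
    hetPenalty <- hetPenalty[.SV_TYPES]
    names(detection) <- names(hetPenalty) <- .SV_TYPES
    detection[is.na(detection)] <- 0.8
    hetPenalty[is.na(hetPenalty)] <- 0
    if (any(detection < 0 | detection > 1) || any(hetPenalty < 0))
        stop("detection probabilities must lie in [0, 1], penalties be >= 0")
    if (fpPerMb < 0 || jitterSd < 0 || sizeErrorSd < 0)
        stop("'fpPerMb', 'jitterSd' and 'sizeErrorSd' must be non-negative")
    structure(list(name = name, detection = detection,
                   hetPenalty = hetPenalty, fpPerMb = fpPerMb,
                   jitterSd = jitterSd, sizeErrorSd = sizeErrorSd,
                   repeatPenalty = repeatPenalty,
                   baseErrorSlope = baseErrorSlope,
                   snpInSvSlope = snpInSvSlope,
                   supportFactor = supportFactor),
              class = "CallerProfile")
}

## Place non-overlapping intervals of the given sizes, avoiding 'avoid'.
## When 'within' is supplied each interval's *start* is drawn inside one of
## those ranges (an SV anchored in a repeat element may extend past it).
## The i-th returned range has width sizes[i] (input order is preserved).
.randomIntervals <- function(seqinfo, sizes, avoid = NULL, within = NULL,
                             maxTries = 80) {
    n <- length(sizes)
    if (!n)
        return(GRanges(seqinfo = seqinfo))
    blocked <- if (is.null(avoid)) GRanges() else reduce(granges(avoid))
    lens <- seqlengths(seqinfo)
    chroms <- seqnames(seqinfo)
    placed <- GRanges(seqinfo = seqinfo)
    todo <- seq_len(n)
    tries <- 0
    while (length(todo) && tries < maxTries) {
        tries <- tries + 1
        sz <- sizes[todo]
        if (is.null(within)) {
            chr <- sample(chroms, length(todo), replace = TRUE, prob = lens)
            maxStart <- lens[chr] - sz + 1
            valid <- maxStart >= 1
            st <- rep(NA_real_, length(todo))
            st[valid] <- floor(runif(sum(valid), 1, maxStart[valid] + 1))
        } else {
            pick <- sample(length(within), length(todo), replace = TRUE,
                           prob = width(within))
            chr <- as.character(seqnames(within))[pick]
            st <- start(within)[pick] +
                floor(runif(length(todo), 0, width(within)[pick]))
            valid <- st + sz - 1 <= lens[chr]
        }
        keep <- which(valid)
        if (!length(keep))
            next
        prop <- GRanges(chr[keep], IRanges(st[keep], width = sz[keep]),
                        seqinfo = seqinfo)
        mcols(prop)$.id <- todo[keep]
        free <- countOverlaps(prop, blocked) == 0 &
            countOverlaps(prop, placed) == 0
        prop <- prop[free]
        if (length(prop) > 1) {
            ## drop later proposals that collide with earlier ones
            o <- order(as.integer(seqnames(prop)), start(prop))
            prop <- prop[o]
            st2 <- start(prop); en2 <- end(prop)
            ch2 <- as.integer(seqnames(prop))
            keep2 <- logical(length(prop))
            curChr <- -1L; curEnd <- -1
            for (k in seq_along(prop)) {
                if (ch2[k] != curChr || st2[k] > curEnd) {
                    keep2[k] <- TRUE
                    curChr <- ch2[k]
                    curEnd <- en2[k]
                }
            }
            prop <- prop[keep2]
        }
        placed <- c(placed, prop)
        todo <- setdiff(todo, mcols(placed)$.id)
    }
    if (length(todo))
        stop("could not place all intervals without overlap; ",
             "use a larger genome or fewer/smaller intervals")
    placed <- placed[order(mcols(placed)$.id)]
    mcols(placed)$.id <- NULL
    placed
}

.logUniformSizes <- function(n, range) {
    round(exp(runif(n, log(range[1]), log(range[2]))))
}

#' Simulate a toy genome with annotation tracks
#'
#' Builds a genome of \code{nChrom} chromosomes together with non-overlapping
#' (within track) repeat (LINE-1-like), exon, assembly-gap and gene tracks.
#' Genes are named and carry logical metadata columns \code{conserved} (a
#' designated highly conserved subset) and \code{family} (a designated
#' expanded-gene-family subset) for the enrichment analyses.
#'
#' @param nChrom number of chromosomes.
#' @param chromLength chromosome length(s) in bp (recycled).
#' @param repeatFraction target fraction of the genome covered by repeats.
#' @param exonFraction target fraction covered by exons.
#' @param gapCount total number of assembly gaps.
#' @param nGenes number of genes.
#' @param geneSizeRange gene length range, bp.
#' @param conservedFraction,familyFraction fractions of genes flagged as
#'   conserved / family members.
#' @param seed optional RNG seed for reproducibility.
#' @return list with \code{seqinfo}, \code{gaps}, \code{repeats},
#'   \code{exons}, \code{genes}.
#' @export
simulateGenome <- function(nChrom = 3, chromLength = 1e6,
                           repeatFraction = 0.10, exonFraction = 0.03,
                           gapCount = 3, nGenes = 60,
                           geneSizeRange = c(2000, 10000),
                           conservedFraction = 0.15, familyFraction = 0.10,
                           seed = NULL) {
    .localSeed(seed)
    if (repeatFraction + exonFraction > 1)
        stop("region fractions sum to more than 1")
    lens <- rep(chromLength, length.out = nChrom)
    si <- Seqinfo(paste0("chr", seq_len(nChrom)), lens)
    total <- sum(lens)
    gaps <- .randomIntervals(si, .logUniformSizes(gapCount, c(5000, 20000)))
    repSizes <- .logUniformSizes(ceiling(repeatFraction * total / 2000),
                                 c(500, 5000))
    repSizes <- repSizes[cumsum(repSizes) <= repeatFraction * total * 1.05]
    repeats <- .randomIntervals(si, repSizes, avoid = gaps)
    exSizes <- rep(200, ceiling(exonFraction * total / 200))
    exons <- .randomIntervals(si, exSizes, avoid = gaps)
    genes <- .randomIntervals(si, .logUniformSizes(nGenes, geneSizeRange),
                              avoid = gaps)
    genes <- genes[sample(length(genes))]   # decouple flags from position
    names(genes) <- sprintf("gene%03d", seq_along(genes))
    nCons <- round(conservedFraction * length(genes))
    nFam <- round(familyFraction * length(genes))
    mcols(genes)$conserved <- seq_along(genes) <= nCons
    mcols(genes)$family <- seq_along(genes) > nCons &
        seq_along(genes) <= nCons + nFam
    genes <- sort(genes)
    list(seqinfo = si, gaps = gaps, repeats = repeats, exons = exons,
         genes = genes)
}

#' Simulate a truth SV panel
#'
#' Plants non-overlapping truth SV on the genome, clear of assembly gaps.  A
#' configurable fraction of them is placed inside repeat regions (all of them
#' in the REP scenario).  Sizes are drawn log-uniformly from the scenario's
#' size range; genotypes follow the scenario's zygosity (\code{"mixed"} draws
#' HOM/HET with equal probability).
#'
#' @param genome a list as returned by \code{\link{simulateGenome}}.
#' @param scenario a \code{\link{scenarioConfig}}.
#' @param seed optional RNG seed.
#' @return an \code{SVCallSet} labelled \code{"truth"} with genotypes set.
#' @export
simulateTruthSv <- function(genome, scenario = scenarioConfig(),
                            seed = NULL) {
    .localSeed(seed)
    counts <- scenario$nSvPerType
    types <- rep(names(counts), counts)
    sizes <- .logUniformSizes(length(types), scenario$sizeRange)
    inRep <- rep(FALSE, length(types))
    nRep <- round(scenario$repetitiveSvFraction * length(types))
    if (nRep > 0)
        inRep[sample(length(types), nRep)] <- TRUE
    spans <- ifelse(types == "INS", 1L, sizes)
    grRep <- if (any(inRep))
        .randomIntervals(genome$seqinfo, spans[inRep], avoid = genome$gaps,
                         within = genome$repeats)
    else GRanges(seqinfo = genome$seqinfo)
    grFree <- if (any(!inRep))
        .randomIntervals(genome$seqinfo, spans[!inRep],
                         avoid = c(granges(genome$gaps), granges(grRep)))
    else GRanges(seqinfo = genome$seqinfo)
    ## restore the original record order (placement preserves input order
    ## within each batch)
    gr <- c(grRep, grFree)[order(c(which(inRep), which(!inRep)))]
    genotype <- switch(scenario$zygosity,
                       HOM = rep("HOM", length(gr)),
                       HET = rep("HET", length(gr)),
                       mixed = sample(c("HOM", "HET"), length(gr),
                                      replace = TRUE))
    SVCallSet(gr, label = "truth", svtype = types, svlen = sizes,
              support = as.integer(round(scenario$coverage)),
              sample = "sim", caller = "truth", genotype = genotype)
}

## effective per-record detection probability under a profile and scenario
.detectionProb <- function(truth, profile, scenario, repeats = NULL) {
    p <- profile$detection[svType(truth)]
    het <- svGenotype(truth) == "HET"
    p[het] <- p[het] - profile$hetPenalty[svType(truth)[het]]
    if (!is.null(repeats) && length(repeats)) {
        inRep <- countOverlaps(svCalls(truth), repeats) > 0
        p[inRep] <- p[inRep] - profile$repeatPenalty
    }
    p <- p - profile$baseErrorSlope *
        max(0, scenario$baseErrorRate - 0.01) / 0.01
    p <- p - profile$snpInSvSlope * scenario$snpInSvFraction
    pmin(pmax(p, 0), 1)
}

#' Emulate an SV caller on a truth panel
#'
#' Call-level surrogate for running a read-based SV caller: each truth SV is
#' detected independently with a type-, zygosity- and context-dependent
#' probability (see \code{\link{callerProfile}}); detected calls receive
#' breakpoint jitter and relative size error; false-positive calls are added
#' at \code{fpPerMb} per Mb, placed uniformly outside the truth intervals with
#' sizes and types resampled from the truth panel; supporting reads are drawn
#' around the scenario coverage (halved for heterozygous events).
#'
#' @param truth truth \code{SVCallSet}.
#' @param profile a \code{\link{callerProfile}}.
#' @param scenario a \code{\link{scenarioConfig}}.
#' @param genome optional genome list (for false-positive placement bounds
#'   and repeat-region penalties); when NULL, FP placement uses the truth
#'   set's seqinfo (which must then carry chromosome lengths).
#' @param seed optional RNG seed.
#' @return an \code{SVCallSet} of emulated calls.
#' @export
emulateCaller <- function(truth, profile, scenario = scenarioConfig(),
                          genome = NULL, seed = NULL) {
    stopifnot(is(truth, "SVCallSet"), inherits(profile, "CallerProfile"))
    .localSeed(seed)
    si <- if (!is.null(genome)) genome$seqinfo else seqinfo(svCalls(truth))
    repeats <- if (!is.null(genome)) genome$repeats else NULL
    p <- .detectionProb(truth, profile, scenario, repeats)
    hit <- rbinom(length(truth), 1L, p) == 1L
    det <- svCalls(truth)[hit]
    if (length(det)) {
        tp <- mcols(det)$svtype
        ins <- tp == "INS"
        shift <- as.integer(round(rnorm(length(det), 0, profile$jitterSd)))
        sizeMul <- pmax(0.1, 1 + rnorm(length(det), 0, profile$sizeErrorSd))
        st <- start(det) + shift
        wd <- pmax(1L, as.integer(round(width(det) * sizeMul)))
        wd[ins] <- 1L
        lens <- seqlengths(si)[as.character(seqnames(det))]
        st <- pmax(1L, st)
        if (!anyNA(lens))
            st <- pmin(st, pmax(1L, lens - wd + 1L))
        det <- GRanges(seqnames(det), IRanges(st, width = wd), seqinfo = si,
                       svtype = tp,
                       svlen = ifelse(ins,
                                      pmax(1, round(mcols(det)$svlen *
                                                    sizeMul)),
                                      wd),
                       support = pmax(1L, rpois(length(det),
                           scenario$coverage * profile$supportFactor *
                               ifelse(mcols(det)$genotype == "HET", 0.5, 1))),
                       sample = mcols(det)$sample,
                       caller = profile$name,
                       genotype = mcols(det)$genotype)
    } else {
        det <- svCalls(truth)[0]
        mcols(det)$caller <- character()
    }
    totalMb <- sum(as.numeric(seqlengths(si))) / 1e6
    nFP <- if (profile$fpPerMb > 0 && !is.na(totalMb) && totalMb > 0)
        rpois(1, profile$fpPerMb * totalMb) else 0L
    if (nFP > 0 && length(truth)) {
        fpType <- sample(svType(truth), nFP, replace = TRUE)
        fpSize <- sample(svLength(truth), nFP, replace = TRUE)
        fpSpan <- ifelse(fpType == "INS", 1L, fpSize)
        avoid <- c(coveredRegions(truth),
                   if (!is.null(genome)) granges(genome$gaps) else GRanges())
        fp <- .randomIntervals(si, fpSpan, avoid = avoid)
        fp <- GRanges(seqnames(fp), ranges(fp), seqinfo = si,
                      svtype = fpType, svlen = as.numeric(fpSize),
                      support = pmax(1L, rpois(nFP, scenario$coverage *
                                                    profile$supportFactor)),
                      sample = unique(c(svSample(truth), "sample1"))[1],
                      caller = profile$name,
                      genotype = "UNKNOWN")
        det <- c(det, fp)
    }
    SVCallSet(det, label = profile$name)
}

#' Simulate a sequenced population with pedigree
#'
#' Draws founder genotypes for a panel of segregating SV under Hardy-Weinberg
#' proportions from the supplied allele frequencies; sons inherit one allele
#' from their sire (Mendelian: transmitted with probability 1 from a
#' homozygous and 0.5 from a heterozygous sire) and one allele from the
#' population.  Each sample's carried SV are then passed through
#' \code{\link{emulateCaller}} once per caller profile.  Per-sample coverage
#' and insert sizes are drawn from ranges typical of 10x cattle resequencing
#' (coverage roughly 3-45 fold around a mean of about 10.8; mean insert size
#' 250-515 bp).
#'
#' @param genome genome list from \code{\link{simulateGenome}}.
#' @param panel truth \code{SVCallSet} of segregating SV.
#' @param alleleFreq numeric vector of allele frequencies in (0, 1], one per
#'   panel record.
#' @param samples character vector of sample ids (founders plus sons).
#' @param pedigree optional \code{data.frame(son, sire)}; sires must be
#'   resolvable before their sons (a cycle is an error).
#' @param profiles named list of \code{\link{callerProfile}}s.
#' @param scenario a \code{\link{scenarioConfig}}.
#' @param seed optional RNG seed.
#' @return list with \code{calls} (per profile: named list of per-sample
#'   \code{SVCallSet}s), \code{genotypes} (samples x panel matrix of allele
#'   counts), \code{meta} (per-sample coverage and insert size).
#' @export
simulatePopulation <- function(genome, panel, alleleFreq, samples,
                               pedigree = NULL,
                               profiles = list(
                                   pem = callerProfile("paired_end_like"),
                                   sr = callerProfile("split_read_like")),
                               scenario = scenarioConfig(), seed = NULL) {
    stopifnot(is(panel, "SVCallSet"))
    .localSeed(seed)
    if (length(alleleFreq) != length(panel))
        stop("'alleleFreq' must have one entry per panel record")
    if (any(alleleFreq <= 0 | alleleFreq > 1))
        stop("allele frequencies must lie in (0, 1]")
    nsv <- length(panel)
    G <- matrix(NA_integer_, nrow = length(samples), ncol = nsv,
                dimnames = list(samples, NULL))
    sons <- if (is.null(pedigree)) character() else pedigree$son
    founders <- setdiff(samples, sons)
    for (s in founders)
        G[s, ] <- rbinom(nsv, 1L, alleleFreq) + rbinom(nsv, 1L, alleleFreq)
    remaining <- setdiff(samples, founders)
    while (length(remaining)) {
        ready <- remaining[vapply(remaining, function(s) {
            sire <- pedigree$sire[match(s, pedigree$son)]
            !(sire %in% samples) || !is.na(G[sire, 1L])
        }, logical(1))]
        if (!length(ready))
            stop("pedigree cycles detected")
        for (s in ready) {
            sire <- pedigree$sire[match(s, pedigree$son)]
            sireAllele <- if (sire %in% samples)
                ifelse(G[sire, ] == 2L, 1L,
                       ifelse(G[sire, ] == 1L, rbinom(nsv, 1L, 0.5), 0L))
            else rbinom(nsv, 1L, alleleFreq)
            G[s, ] <- sireAllele + rbinom(nsv, 1L, alleleFreq)
        }
        remaining <- setdiff(remaining, ready)
    }
    meta <- data.frame(
        sample = samples,
        sire = if (is.null(pedigree)) NA_character_
               else pedigree$sire[match(samples, pedigree$son)],
        coverage = pmin(pmax(stats::rlnorm(length(samples),
                                           log(10.5), 0.3), 3.2), 44.5),
        insert_size = pmin(pmax(round(rnorm(length(samples), 350, 40)),
                                250), 515))
    calls <- lapply(profiles, function(pr) {
        out <- lapply(samples, function(s) {
            carried <- which(G[s, ] > 0)
            sub <- panel[carried]
            gr <- svCalls(sub)
            mcols(gr)$sample <- rep(s, length(gr))
            mcols(gr)$genotype <- ifelse(G[s, carried] == 2L, "HOM", "HET")
            emulateCaller(SVCallSet(gr, label = s), pr, scenario,
                          genome = genome)
        })
        names(out) <- samples
        out
    })
    list(calls = calls, genotypes = G, meta = meta)
}

#' Simulate twice-sequenced individuals
#'
#' For each individual, emulates two independent sequencing runs of the same
#' truth panel and a third call set from the pooled evidence of both runs
#' (detection probability \code{1 - (1 - p)^2}, the chance that at least one
#' run's evidence supports the SV).  Replicate insert sizes are drawn so that
#' a configurable number of individuals violate the 5 bp merge-eligibility
#' rule.
#'
#' @param truth truth \code{SVCallSet} carried by every individual.
#' @param profile a \code{\link{callerProfile}}.
#' @param nIndividuals number of twice-sequenced individuals.
#' @param nIneligible number of individuals whose two runs differ by more
#'   than 5 bp in mean insert size (default: a quarter, rounded).
#' @param scenario a \code{\link{scenarioConfig}}.
#' @param genome optional genome list passed to the emulation.
#' @param seed optional RNG seed.
#' @return list with one element per individual: \code{rep1}, \code{rep2},
#'   \code{merged} (\code{SVCallSet}s), \code{insert1}, \code{insert2},
#'   \code{merge_eligible}; plus attribute \code{"meta"} summarising insert
#'   sizes and eligibility.
#' @export
simulateTwiceSequenced <- function(truth, profile, nIndividuals = 28,
                                   nIneligible = round(nIndividuals / 4),
                                   scenario = scenarioConfig(),
                                   genome = NULL, seed = NULL) {
    stopifnot(is(truth, "SVCallSet"), inherits(profile, "CallerProfile"))
    .localSeed(seed)
    merged <- profile
    merged$detection <- 1 - (1 - profile$detection)^2
    merged$hetPenalty <- pmax(
        0, merged$detection -
           (1 - (1 - (profile$detection - profile$hetPenalty))^2))
    merged$name <- paste0(profile$name, "_merged")
    ineligible <- seq_len(nIndividuals) %in%
        sample(nIndividuals, min(nIneligible, nIndividuals))
    out <- vector("list", nIndividuals)
    meta <- data.frame(individual = sprintf("ind%02d", seq_len(nIndividuals)),
                       insert1 = NA_real_, insert2 = NA_real_,
                       merge_eligible = NA)
    for (i in seq_len(nIndividuals)) {
        base <- round(rnorm(1, scenario$insertSizeMean,
                            scenario$insertSizeSd / 2))
        gap <- if (ineligible[i]) runif(1, 6, 20) else runif(1, 0, 5)
        ins2 <- round(base + sign(runif(1) - 0.5) * gap)
        gr <- svCalls(truth)
        mcols(gr)$sample <- rep(meta$individual[i], length(gr))
        tr <- SVCallSet(gr, label = meta$individual[i])
        out[[i]] <- list(
            rep1 = emulateCaller(tr, profile, scenario, genome = genome),
            rep2 = emulateCaller(tr, profile, scenario, genome = genome),
            merged = emulateCaller(tr, merged, scenario, genome = genome),
            insert1 = base, insert2 = ins2,
            merge_eligible = abs(base - ins2) <= 5)
        meta$insert1[i] <- base
        meta$insert2[i] <- ins2
        meta$merge_eligible[i] <- out[[i]]$merge_eligible
    }
    names(out) <- meta$individual
    attr(out, "meta") <- meta
    out
}

#' Filter twice-sequenced individuals by the insert-size merge rule
#'
#' Pooling the reads of two runs is only sensible when their insert-size
#' distributions agree; individuals whose mean insert sizes differ by more
#' than \code{maxDiff} bp are excluded.
#'
#' @param meta data.frame with columns \code{insert1}, \code{insert2} (e.g.
#'   the \code{"meta"} attribute of \code{\link{simulateTwiceSequenced}}).
#' @param maxDiff maximum tolerated difference, bp (default 5).
#' @return logical vector marking merge-eligible individuals.
#' @export
mergeEligible <- function(meta, maxDiff = 5) {
    abs(meta$insert1 - meta$insert2) <= maxDiff
}
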