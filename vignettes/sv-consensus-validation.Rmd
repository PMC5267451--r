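---
title: "Consensus calling, validation and enrichment analysis of structural variants"
author: "svconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus calling, validation and enrichment analysis of structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svconcord)
library(GenomicRanges)
```

## The problem

Structural variants (SV) — deletions (DEL), insertions (INS), inversions
(INV) and tandem duplications (DUP) — are called from short-read whole-genome
sequence with a high false-positive rate, because each detection strategy
(paired-end mapping anomalies, split reads) has its own failure modes.  A
well-established remedy in cattle and other livestock resequencing work is to
accept only calls supported by *two* complementary callers and then to
validate the surviving catalogue with orthogonal evidence: repeated
sequencing of the same animal, and Mendelian transmission from sire to son.
`svconcord` implements that whole workflow — the filters, the dual-caller
intersection, the two validation designs, a simulation benchmark, and the
downstream gene-set / LINE-1 enrichment statistics — together with a
synthetic-data module so every stage can be exercised at desk scale.

## Data model

All call sets are `SVCallSet` objects: a sorted `GRanges` with metadata
columns `svtype`, `svlen`, `support`, `sample`, `caller`, `genotype`.
Coordinates are 1-based closed, the native `GRanges` convention; BED input
(0-based half-open) and caller tables (1-based) are converted at the I/O
boundary, so there is exactly one conversion point in the package.  An
insertion occupies a single base at its breakpoint (`width == 1`) and carries
the inserted length in `svlen`; all other types satisfy
`svlen == end - start + 1`.

Because insertions have no reference span, every interval rule needs an
insertion reading.  We use one consistently: two insertions match when their
breakpoints lie within a window of 25 bp (the same threshold as the
consensus overlap rule), and an insertion contributes its inserted length —
not a reference span — to covered-length totals.  This is the only reading
under which per-type covered lengths of a catalogue containing insertions
add up sensibly.

## The consensus pipeline

`filterRawCalls()` applies, in order:

1. **support filter** — at least 4 supporting read pairs (default);
2. **gap filter** — any call overlapping an assembly gap by ≥ 1 bp is
   removed (gap regions in a reference assembly attract alignment
   artefacts);
3. **maximum-support cap** (optional, meant for split-read-style sets) —
   calls with more supporting reads than 2× the sample's coverage (4× for
   duplications, which legitimately attract extra reads) are removed as
   collapsed-repeat pile-ups;
4. **recurrence filter** — an SV must be observed in at least 2 individuals.
   "The same SV in two samples" is defined as same type with ≥ 50%
   reciprocal overlap (breakpoints within 25 bp for insertions); records are
   clustered under that relation and clusters seen in fewer than
   `minIndividuals` samples are dropped.  The 50% reciprocal threshold
   deliberately reuses the matching notion of the benchmark layer rather
   than introducing a second arbitrary constant.

`intersectCallers()` then keeps only SV reported by both callers: records of
equal type, same sample, overlapping by at least 25 bp are matched
one-to-one.  Matching is greedy by descending overlap with a deterministic
tie-break (ascending chromosome and start of both records), which makes the
output independent of input record order.  Each match emits a consensus
record spanning the intersection with the smaller of the two support counts.
Filters run before the intersection, matching the order in which the
pipeline stages are described for the empirical data; both stages are plain
functions, so the order can be changed by the caller if desired.

Whether the observed dual-caller overlap exceeds chance is tested by
`expectedOverlapTest()`: per chromosome, the chance expectation is the
product of the two callers' coverage proportions, and a paired t-test across
chromosomes compares observed overlap proportions against these products
(one-sided, observed greater, by default).

Coverage accounting (`populationSummary()`, `sharedCoverage()`) reports
per-type union covered lengths; the total is the *sum of the four per-type
lengths*, not a cross-type union — a region carrying both a deletion and a
duplication counts once per type.  This convention is required to reproduce
the row sums of published per-type coverage tables.

## Validation designs

* **Twice-sequenced** (`twiceSequencedValidate()`): two independent
  sequencing runs of one animal should support the same SV; only records
  matched across both replicate call sets (same 25 bp rule) are kept.
* **Merge concordance** (`mergeOverlapConcordance()`): when the two runs'
  read sets are pooled instead, a separate call set results; the share of
  calls common to the pooled-evidence set and the replicate-overlap set,
  divided by the smaller set, measures their concordance.  Pooling is only
  meaningful when the two libraries are comparable, so `mergeEligible()`
  filters individuals whose mean insert sizes differ by more than 5 bp.
* **Transmission** (`transmissionValidate()`): an SV carried by a sire is
  transmitted to a son with probability 1 (homozygous) or 0.5
  (heterozygous), so a son call matched by a sire call in at least one pair
  is Mendelian-consistent.  SV validated through several pairs are
  de-duplicated by 50% reciprocal-overlap clustering; the threshold is a
  package choice, made to match the recurrence filter.
* **Chip comparison** (`compareWithChipCnv()`): SNP arrays only resolve
  large unbalanced events, so sequence calls are compared with chip CNV only
  for DEL/DUP longer than 5 kb, with any (≥ 1 bp) overlap counting as
  confirmation.  A chip set containing inversions is rejected — arrays
  cannot see balanced events.

## Benchmarking against simulated truth

A call is a true positive when it covers at least 50% *of the truth SV's
length* (`matchCallsToTruth()`, one-to-one, greedy by descending fraction).
The published rule does not say whether the 50% is truth-relative or
reciprocal; we default to the literal truth-relative reading and expose
`mode = "reciprocal"`.  Precision is TP / calls (undefined, not zero, when
there are no calls) and sensitivity TP / truth.  Across replicates,
`evaluateScenario()` averages counts first and then takes ratios
(ratio-of-means), matching the averaging convention under which such
benchmark figures are usually reported; mean-of-ratios is available as an
option.

## Enrichment statistics

* `genesOverlappingSv()` reports a gene when a *single* SV overlaps it by at
  least 50 bp (summing across SV is available via `perSv = FALSE`; the
  per-SV rule is the stricter reading) and flags genes completely
  encompassed by an SV.
* `chisq2x2()` is the Pearson chi-square on the 2×2 gene-set × SV-status
  table, *without* continuity correction — the uncorrected statistic is the
  one that reproduces the published worked examples, which we take as the
  definition.
* `regionSvProportion()` / `regionEnrichment()` compare the SV-covered
  proportion of focal regions (e.g. LINE-1 elements) with the background
  (genome minus focal minus excluded regions such as exons; assembly gaps
  are worth excluding too since filtered catalogues cannot cover them).
  `pairedTTest()` across call sets tests enrichment; the published table we
  reproduce reports the one-sided p-value in the direction of the observed
  mean difference, so the helper takes an `alternative` argument and our
  reproduction test selects the observed direction per SV type.

## The synthetic-data module

The generators produce every input the pipeline needs, at the call level —
no reads are simulated.  The published benchmark simulated reads and ran the
real callers; re-running those tools is out of scope here, so the module
instead emulates caller *behaviour* with parameters expressing the same
findings:

* `simulateGenome()` builds a toy genome (default 3 × 1 Mb) with
  non-overlapping (within track) assembly gaps, repeat (LINE-1-like) regions
  (10% of the genome), exons and named genes with designated conserved and
  gene-family subsets.
* `simulateTruthSv()` plants non-overlapping truth SV clear of gaps — by
  default 100 each of DEL/INV/DUP, the standard scenario size.  Sizes are
  log-uniform on 100 bp–10 kb (the published catalogue spans 25 bp–44 kb;
  the distribution itself is not stated, so this default was chosen once as
  a realistic spread and is configurable).  Scenario presets mirror the
  published simulation grid: `HOM`, `HET` (coverage 5 per haplotype — two
  rearranged haplotypes of 50 SV each pooled to 10×), `REP` (all SV in
  repeats; an SV is "in" a repeat when it is anchored there, since SV are
  frequently larger than a single repeat element) and `MIX` (heterozygous,
  SNP-in-SV fraction 0.01, genome-wide SNP rate 0.008, half of SV in
  repeats).
* `emulateCaller()` detects each truth SV independently with a type- and
  zygosity-dependent probability, then applies breakpoint jitter
  (Gaussian, default sd 10 bp), relative size error (default sd 5%) and
  uniform false positives (`fpPerMb`).  The two presets encode the
  complementary strategies: the paired-end-like profile detects 87% of
  inversions and is nearly zygosity-blind; the split-read-like profile
  detects 58% of inversions and loses 35 / 8.5 / 5.15 percentage points of
  DEL / INV / DUP sensitivity on heterozygotes — the published heterozygote
  deficits.  The scenario's base-error and SNP-in-SV rates map to additive
  detection penalties (`baseErrorSlope`, `snpInSvSlope`), and repeat
  regions to an additive `repeatPenalty`; these linear mappings are the
  module's own modelling choice, chosen for transparency rather than
  realism of the functional form.
* `simulatePopulation()` draws founder genotypes under Hardy–Weinberg from
  per-SV allele frequencies; sons inherit one allele from the sire
  (probability 0.5 if heterozygous) and one from the population.  Coverage
  and insert sizes are drawn within the ranges typical of the resequencing
  datasets this workflow targets (about 3–45× around a mean of 10.8;
  insert sizes 250–515 bp).
* `simulateTwiceSequenced()` emulates two independent runs plus a
  pooled-evidence ("merged") call set whose detection probability is
  `1 - (1 - p)^2` — the chance that at least one run's evidence supports
  the SV — and draws replicate insert sizes so a configured number of
  individuals (default a quarter) violate the 5 bp merge rule.

What passing tests on these data do and do not show: the generators produce
exactly the independence and Mendelian structure the validation designs
assume, so recovery of configured rates demonstrates the *pipeline's*
correctness, not the callers'.  Real data add alignment artefacts, clustered
(non-uniform) false positives, breakpoint biases and genotyping error that
the emulation does not model; absolute precision/sensitivity numbers from
the synthetic benchmark therefore do not transfer to real callers.

## Numerical choices and degenerate inputs

* Greedy one-to-one matching everywhere, with the deterministic tie-break
  (descending score, then ascending coordinates) that makes results
  order-invariant; a maximum-cardinality matching was rejected as needless
  complexity for TP counting, where conflicts are rare and the greedy
  choice is the published operational rule ("overlapping calls are paired").
* `precision` with zero calls is reported missing (NA), never 0; zero truth
  variants or zero-variance t-test differences are errors, not silent
  results.
* Chi-square requires all four marginals positive; fold change with a zero
  background is NA with a warning.
* Interval placement in the simulators retries a bounded number of batches
  and fails with advice to enlarge the genome rather than looping forever.
* Repeated coverage-proportion computations (thousands of simulated sets in
  the calibration tests) run through a linearized sort/cumsum sweep rather
  than repeated `GRanges` set operations; both routes are exact and the
  test suite checks coverage arithmetic against a per-base mask oracle.

## Problem sizes used by the test suite

The acceptance-style checks run at desk scale, chosen once: 2 × 2 Mb
genomes; 100–300 truth SV per scenario; 100 emulation replicates for rate
recovery; 200 seeded scenarios for the consensus precision/sensitivity
trade-off; 1000 trios for the Mendelian property; 1000 simulations for the
null calibration of the LINE-1 test (5 random call sets of 300 SV each per
simulation, with chromosome-end zones excluded from the background because
uniform placement of whole SV under-covers the ends).

## Known limitations

* Translocations (CTX/ITX) are parsed but excluded — only one of the two
  caller strategies reports them, so they can never reach the consensus set.
* The emulation's penalty mappings are linear and additive; they reproduce
  reported *deltas*, not mechanism.
* `mergeOverlapConcordance()` is computed per individual; no attempt is made
  to model why pooled-evidence and replicate-overlap sets differ beyond the
  doubled-coverage detection boost.
* The published LINE-1 table's insertion and inversion p-values cannot be
  reproduced exactly from its printed six-decimal proportions (the
  proportions are of order 10^-6–10^-3, so printing truncates most of the
  information); the reproduction test documents the two achievable matches
  (deletions, duplications) and the two rounding-limited ones.
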