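Package: svconcord
Title: Consensus Calling, Validation and Enrichment Analysis of Structural Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds high-confidence structural-variant (SV) catalogues from the
    output of two complementary SV callers (paired-end-mapping style and
    split-read style) by support/recurrence filtering, assembly-gap exclusion
    and dual-caller overlap intersection; validates call sets by twice-sequenced
    replicate concordance and sire-son Mendelian transmission; benchmarks
    precision and sensitivity against simulated truth panels; and tests gene
    sets and LINE-1 regions for SV depletion or enrichment with 2x2 chi-square
    and paired t statistics. A synthetic-data module generates toy genomes,
    truth SV panels, emulated caller outputs, populations with pedigrees and
    twice-sequenced replicates so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: StructuralVariation, CopyNumberVariation, VariantDetection, Genetics
RoxygenNote: 7.3.3
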