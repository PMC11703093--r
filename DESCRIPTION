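Package: recfin
Title: Recombination Landscapes, PRDM9 Zinc-Finger Diversity and Motif
    Erosion in Fish Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of linkage-disequilibrium
    based recombination maps in fish populations: reading and smoothing
    per-interval population recombination rate (rho = 4*Ne*r) maps,
    calling recombination hotspots against local flanking backgrounds,
    quantifying landscape heterogeneity and broad-scale chromosomal
    profiles, measuring recombination enrichment relative to genomic
    features with a CpG-island predictor suited to fish genomes, testing
    hotspot sharing between populations with a masked random-placement
    permutation null, cataloguing PRDM9 zinc-finger array alleles and
    their per-position amino-acid diversity, and scanning genomes with
    position weight matrices at exact p-value thresholds to test for
    between-lineage binding-motif erosion. A seeded synthetic-data
    generator reproduces the statistical structure these analyses assume
    (gamma-distributed background rates, telomere-elevated broad-scale
    rates, planted kilobase-scale hotspots, hypervariable zinc-finger
    alleles, lineages with partially disrupted motif instances) so every
    stage is testable without population resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
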