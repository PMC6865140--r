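Package: PopExome
Title: Population-Aware Exome Variant Analysis and Cohort Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-aware analysis of exome cohorts: quality
    filtering of multi-sample VCF genotype panels restricted to a target
    region, functional consequence classification of single-nucleotide
    variants from gene models and reference sequence (stop-gain, stop-loss,
    splice-site, missense, synonymous), cross-population allele frequency
    statistics (overlap, novelty, rarity classes, maximum minor allele
    frequency across panels), detection of population-specific variants
    enriched by founder effects, gene prioritization by variant burden and
    intolerance scores, and incidental-finding and case-cohort screening
    with configurable filter cascades. Includes a synthetic multi-population
    cohort generator (Balding-Nichols allele frequency divergence,
    Hardy-Weinberg genotypes, truth-labelled consequence variants and
    deleteriousness scores) so that every stage of the pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
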