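Package: isofilter
Title: Cross-Platform Consensus Filtering of Strain-Distinguishing Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distills a jointly genotyped multi-sample VCF from two nearly
    isogenic inbred lines sequenced on three platforms into high-confidence
    strain-distinguishing variants. Implements a ten-step hard-filter cascade
    (depth bounds, per-strain best-call comparison, uncertain-call and
    low-quality-discordance removal, pooled allele-balance, cross-platform
    dispute, Phred-quality tiers, and a homopolymer deletion-artifact filter
    evaluated on the reference sequence), with a per-variant elimination
    trace. Downstream helpers classify variants (transition, transversion,
    insertion, deletion), build per-strain summary tables, binned density
    tracks and kilobase-scale cluster calls, aggregate SnpEff annotations
    (effect-category tabulation, high/moderate-impact extraction, nearest-gene
    set arithmetic, gene-list proximity overlap), and score targeted
    re-sequencing genotypes against predicted strain-specific variants. A
    seeded synthetic-data module generates reference sequences, joint VCFs
    with planted variant classes and machine-readable truth tables, annotated
    fixtures, and validation genotype matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
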