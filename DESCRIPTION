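Package: rddcascade
Title: Detection and Filtering of RNA-DNA Differences from Matched DNA and RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of candidate RNA-editing sites (RNA-DNA
    differences, RDDs) from matched DNA and RNA sequencing of biological
    replicates. Implements per-replicate calling of positions that are
    homozygous in DNA but heterozygous in RNA, followed by an ordered
    cascade of artifact filters (read-depth, replicate support, read-end
    position, strand bias, biallelic status, non-coding splice regions,
    homopolymers, and a genomic-read pattern search against unassembled
    paralogs), with per-stage accounting. Downstream characterization
    covers the base-change spectrum with canonical A-to-I collapsing,
    clustering of nearby edited sites, gene and consequence summaries,
    and a two-way analysis of variance of editing levels across tissues
    and developmental stages. A seedable simulator generates toy genomes,
    annotation and pileup observations with planted true edits and every
    artifact class the cascade targets, so the pipeline can be validated
    against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
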