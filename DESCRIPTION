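Package: epimapr
Title: Integrative Epigenomic Analysis of Two-Genotype Oocyte Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream integrative analysis of histone-mark
    ChIP-seq, whole-genome bisulfite methylation and expression data from a
    wild-type versus knockout comparison: RPKM quantification of signal over
    genomic bins, peaks and promoters; combinatorial chromatin-state
    classification of promoters (H3K4me3/H3K27me3/H2AK119ub1); a six-class
    taxonomy of 10-kb bins by directional Polycomb-mark change between
    genotypes; context- and element-resolved DNA-methylation summaries
    including imprinting control regions and spike-in conversion efficiency;
    TSS-anchored enrichment profiles; and fold-change differential expression.
    A synthetic-data generator plants known chromatin states, methylation
    domains and expression effects so every stage can be validated against
    ground truth.
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
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    withr,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
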