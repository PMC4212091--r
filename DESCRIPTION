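Package: mapbias
Title: Allelic Mapping Bias Detection and Correction for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects allelic mapping bias in RNA-seq by exhaustive
    haplotype-aware read simulation, catalogs biased read start sites,
    filters biased alignments, and quantifies the downstream effect of
    that filtering on exon quantification and cis-eQTL discovery with
    permutation-based FDR control. Includes a synthetic-data generator
    that builds small genomes with segmental duplications, phased
    variant panels, multi-exon gene models and RNA-seq cohorts with
    planted true and mapping-bias-driven false eQTLs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readr,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
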