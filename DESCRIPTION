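Package: lrtq
Title: Likelihood Ratio Tests for Rare-Variant Effects on Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level association testing between sets of rare variants and
    quantitative traits such as gene expression. Implements a likelihood ratio
    test that weights variants by causal priors derived from functional
    annotation and aggregates per-variant evidence nonlinearly, with fixed and
    adaptive permutation p-values. Also provides re-implementations of standard
    rare-variant tests (CMC, WSS, burden, variable threshold, ACAT-V, ACAT-O,
    SKAT and SKAT-O with a moment-matching null approximation), a simulation
    study harness for type-I error and power, and an eQTL-style pipeline for
    rare-variant eGene discovery: TSS-window variant grouping, annotation-based
    weighting schemes, covariate residualization with rank-based inverse normal
    transformation, FDR eGene calling, tissue-sharing summaries, expression
    outlier detection and enrichment statistics. Includes VCF genotype readers
    with quality-control filters and a synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
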