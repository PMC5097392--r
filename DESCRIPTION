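Package: methcopd
Title: Differential Methylation and Comethylation Network Analysis of
    Whole-Blood Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for case-control epigenome-wide
    association studies on Illumina 27K-style whole-blood methylation
    arrays: probe- and sample-level quality control with an auditable
    removal ledger, beta and M-value transforms, reference-based
    cell-type deconvolution by constrained projection, per-CpG linear
    modelling with empirical-Bayes variance moderation and
    Benjamini-Hochberg false discovery rate control, a qualitative
    cross-cohort test-statistic-difference screen, signed weighted
    comethylation network analysis (soft-thresholded adjacency,
    topological overlap, module detection, eigengenes, module-trait
    association, gene significance and module membership), and
    hypergeometric gene-set enrichment. Includes a synthetic two-cohort
    data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
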