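Package: coexcomp
Title: Two-Cohort Gene Co-Expression Network Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing bulk RNA-seq transcriptomes of two
    patient cohorts (for example early- versus late-onset Alzheimer's disease,
    split at an age-at-diagnosis cutoff) at the co-expression network level.
    Provides trimmed-mean-of-M-values normalization and a negative-binomial
    conditional exact test for differential expression, fold-change based
    gene-set perturbation scoring with separate up/down tests, mutual-information
    co-expression network inference with equal-frequency discretization,
    analytic G-statistic edge significance and percentile thresholding,
    two-level map-equation community detection with multi-trial greedy search,
    hypergeometric module over-representation analysis with Benjamini-Hochberg
    control and bipartite module-function networks, and degree-distribution
    comparison statistics (Pearson chi-squared and Cramer's V). A synthetic-data
    generator with planted modules, differentially expressed genes and perturbed
    gene sets provides ground truth for every stage.
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
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
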