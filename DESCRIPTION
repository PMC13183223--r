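Package: nettox
Title: Network Toxicology Target Triage with Robustness Validation
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links chemical-exposure target lists to disease transcriptomes
    through a tested, fully seeded pipeline: empirical-Bayes moderated
    differential expression, context-aware target-list filtering, three-way
    list intersection with hypergeometric and permutation overlap statistics,
    composite centrality ranking of protein-protein interaction networks,
    tri-algorithm consensus feature selection (L1-penalized logistic
    regression, gradient-boosted trees, shadow-feature comparison) with
    nested cross-validation and bootstrap stability estimates, two-cohort
    rank-sum validation, fold-change sensitivity grids, and group-difference
    testing for immune-composition tables. Ships a synthetic-data generator
    that plants recoverable differential genes, database targets, and network
    hubs so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    glmnet,
    xgboost,
    ranger,
    jsonlite,
    yaml,
    withr
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
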