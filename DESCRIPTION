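Package: invadome
Title: Regional Differential Proteomics of Tumor Core Versus Invasive Rim
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable pipeline for label-free quantitative proteomics of
    patient-derived xenografts microdissected into a vascularized tumor core
    ("angiogenic", A) and an invasive rim (I), with the human (tumor) and
    mouse (stroma) proteomes analyzed as parallel compartments. Implements
    replicate-reproducibility filtering by coefficient of variation,
    presence-based aggregation across biological samples, median-ratio
    normalization, low-quantile imputation, Welch t-tests with
    Benjamini-Hochberg correction and log2 fold-change flagging, Ward-D2
    hierarchical clustering with bootstrap branch support, hypergeometric
    over-representation analysis against GMT gene-set collections, a
    from-scratch Markov Cluster Algorithm for confidence-weighted interaction
    networks, and literature-keyword AngioScore comparison of top hits. A
    synthetic dual-species data generator with planted ground truth makes the
    whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    stats,
    utils,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
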