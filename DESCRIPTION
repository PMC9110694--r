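Package: urigest
Title: Gestational Age Prediction from Untargeted Urine Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for predicting gestational age
    at sample collection from untargeted LC-MS urine metabolomics feature
    tables. Implements QC-driven preprocessing (blank filtering, dilution
    linearity filtering, presence filtering, per-batch LOESS signal-drift
    correction on pooled QC injections, probabilistic quotient
    normalization, low-value imputation, and technical-replicate
    aggregation), random-forest regression with external leave-one-out
    cross-validation, parsimonious restricted-model selection, stratified
    term/preterm modelling, univariate association screening, pathway
    over-representation, Spearman correlation networks with betweenness
    centrality, and MS/MS spectral-library annotation by forward
    dot-product matching. A seeded synthetic-cohort generator emulating the
    statistical structure of a multi-site pregnancy cohort makes every
    stage testable without access to instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ranger,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
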