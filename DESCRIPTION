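Package: gaknn
Title: Drug Sensitivity Prediction from Transcriptomes with GA/kNN Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns gene-expression signatures of drug sensitivity from
    cancer cell lines and transfers them to tissue samples. For each drug,
    a genetic algorithm searches for fixed-size gene sets whose expression
    profiles predict observed ln(IC50) values under a k-nearest-neighbour
    regression rule with leave-one-out squared-error fitness; repeated
    Monte-Carlo 90/10 cross-validation yields aggregated predictions,
    predictability calls, and gene-importance rankings by selection
    frequency. Fitted models impute ln(IC50) for external tumour and
    normal samples and drive tumour-type specificity, tumour-versus-normal,
    subtype-differential, and mutation-group statistics. Includes readers
    for TSV and GCT expression matrices, GDSC-style response tables with
    release merging, per-sample Z-score integration, and a seeded synthetic
    data generator with planted signal genes for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
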