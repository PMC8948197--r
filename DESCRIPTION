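Package: imflux
Title: Pathway Flux Analysis and an Immune-Related Diagnostic Index from
    Blood Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes per-pathway mass-action fluxes from bulk gene-expression
    profiles over a layered knowledge network (genes, species, typed reactions,
    pathways with crosstalk), summarises signaling-transduction and
    energy-metabolism fluxes into a single immune-related diagnostic score
    (the IM-Index), and provides the rank-based statistical battery used to
    evaluate such scores: Kruskal-Wallis and Wilcoxon group tests, midrank
    ROC/AUC with stratified bootstrap confidence intervals, one-sided
    bootstrap classifier comparison, logistic odds ratios and Spearman
    correlation against biomarkers, and per-pathway differential flux with
    Bonferroni correction. Includes a synthetic-data module that generates
    miniature knowledge networks and three-group lognormal expression cohorts
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyselect,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
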