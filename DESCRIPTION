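Package: modregnet
Title: Module Mining and Regulator Inference for Case-Control Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discovering candidate disease modules
    and their upstream regulators from case-control expression data. Calls
    differentially expressed genes with a moderated t statistic, builds a
    score-weighted interaction network restricted to those genes, ranks hub
    genes by the W statistic (|logFC| * -log10(p) * degree), mines overlapping
    cohesive modules with a ClusterONE-style greedy search, tests modules for
    gene-set over-representation and for targeting by non-coding RNAs and
    transcription factors via the hypergeometric test, filters TF-target pairs
    by expression correlation, and validates hub genes in an independent
    cohort with moderated t tests and ROC curves. Ships a synthetic-data
    generator with planted differential expression, planted cohesive modules,
    planted enriched terms and planted regulators, so the whole pipeline is
    testable end-to-end without external databases.
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
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    limma,
    fgsea,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
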