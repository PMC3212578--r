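Package: arscore
Title: Rank-Based Pathway Activity Scoring and Co-Regulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-sample pathway activity from gene expression
    matrices using the normalized average rank of gene-set members
    (AR-score) and a Kolmogorov-Smirnov-style enrichment score (ES);
    builds pathway co-regulation networks from Spearman correlations of
    activity profiles with shared genes excluded; identifies
    differentially active pathways between sample groups with Storey
    q-value FDR control; quantifies within-pathway gene co-expression;
    clusters and classifies samples on activity profiles (complete
    linkage, linear SVM with leave-one-out cross-validation); and
    simulates expression data with known pathway structure so every
    stage can be validated offline. Reads GMT gene sets and TSV or GCT
    1.2 expression matrices; ships a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
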