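Package: stromadev
Title: Integrative Multi-Omics Analysis of Lymph Node Stromal Cell Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrative analysis of non-endothelial lymph node
    stromal cells across development and conditions: single-cell RNA-seq
    quality control, normalization, covariate regression, graph clustering and
    per-subset differential expression; branching pseudotime on a principal
    tree with branch-point differential expression; detection of
    differentially methylated regions from whole-genome bisulfite data via
    coverage-weighted smoothing and kernel t-statistics; differential
    chromatin accessibility with median-of-ratios normalization and a
    negative-binomial Wald test; joint classification of genes by concordance
    of expression and accessibility changes; promoter motif enrichment and
    transcription-factor nomination at trajectory branch points; dynamical
    gene-regulatory-network inference from pseudotemporally ordered
    expression; and cumulative Z-score matching of overexpression signatures
    to stromal subsets. Includes seeded synthetic-data generators with planted
    ground truth for every input type.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    randomForest,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
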