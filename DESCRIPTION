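Package: cellcascade
Title: Hierarchical, Timepoint-Aware Cell-Type Annotation for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains one gradient-boosted tree classifier per layer of a
    user-supplied annotation hierarchy and cascades query cells down that
    hierarchy, assigning a label at each layer only when the maximum class
    probability clears a rejection threshold (default 0.5). Layers may be
    partitioned by developmental timepoint so that stage-restricted cell
    subtypes are only predicted within their stage. Per-class marker genes
    are ranked by exact tree-path Shapley attributions. Includes expression
    matrix readers (CSV and MatrixMarket), counts-per-10k log normalization,
    gene alignment with explicit missing-gene handling, file-driven ortholog
    mapping for cross-species prediction, stratified hold-out and repeated
    reshuffled cross-validation with confusion matrices, a portable trained
    model bundle format, a negative-binomial synthetic-data generator with
    planted hierarchical markers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    xgboost (>= 1.7),
    jsonlite,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
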