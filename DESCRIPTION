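Package: diffact
Title: Differentiation-Network Activity Scoring for Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-cell pluripotency from single-cell RNA-seq
    expression matrices as the activity of the cell-differentiation
    protein-protein interaction (PPI) network. Each network edge is weighted
    by the mass-action product of its two participants' expression levels and
    the per-cell activity score is the sum of all edge weights, min-max scaled
    across cells. Includes the network-construction pipeline (GO-annotation
    protein catalog crossed with a SIF interaction dump), standard single-cell
    preprocessing (cell/gene filtering, log-normalization, an offset
    log-normalization variant for zero-free matrices, vst-style highly
    variable feature selection), a fast HVF approximation of the score,
    a synthetic-data generator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    Seurat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
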