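Package: scPotency
Title: Single-Cell Differentiation Potency from Signaling Entropy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the differentiation potency of single cells as the
    normalized entropy rate of an expression-weighted random walk on a
    protein-protein interaction network, infers discrete potency states by
    Gaussian-mixture modelling of logit-transformed potency with BIC model
    selection, combines potency states with density-based cell-type clusters
    into cell-states and cell-density landscapes, selects a maximal-potency
    root cell and orders cells by diffusion pseudotime, and provides the
    accompanying signature and enrichment statistics (potency-associated
    differential expression, signed signature scoring, cell-cycle scores,
    rank-based gene-set enrichment with a Monte-Carlo null). Includes seeded
    synthetic-data generators with known ground truth for networks,
    potency-graded expression matrices, bifurcating trajectories and
    droplet-style count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    mclust,
    Rtsne,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
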