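Package: eecfate
Title: Lineage Trajectories and Transcription Factor Activity Inference for
    Enteroendocrine Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the analysis of plate-based single-cell
    RNA-seq data of differentiating enteroendocrine cells: quality control and
    total-count normalization, highly-variable-gene selection, PCA, (batch
    balanced) nearest-neighbor graphs, graph clustering, cluster-level lineage
    abstraction and diffusion pseudotime, a potential-energy-biased Markov
    chain trajectory engine with exact absorption (fate) probabilities,
    inference of per-cell transcription factor activities by a ridge linear
    model of motif-target regulation, and selection of lineage-specific
    regulators by z-score, trajectory variability, and lagged
    expression-activity correlation. A synthetic-data generator with a planted
    branching lineage, planted pseudotime, and planted regulators makes every
    stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    digest,
    uwot,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
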