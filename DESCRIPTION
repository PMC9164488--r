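Package: spanet
Title: Adversarial Variational Graph Autoencoders for Cell-Cell
    Interaction Networks from Single-Cell Spatial Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs denoised and completed cell-cell interaction
    networks from single-cell spatial transcriptome snapshots. An
    expression matrix and a proximity-derived cell adjacency graph are
    fed to a variational graph autoencoder whose latent space is
    regularized by an adversarial discriminator; the inner-product
    decoder returns interaction probabilities for every cell pair,
    including distal pairs never observed as direct contacts. The
    package also provides the surrounding toolkit: k-nearest-neighbor
    spatial graph construction, edge train/test splitting with negative
    sampling, corruption benchmarks (expression noise, dropout, edge
    deletion and insertion, tissue cropping), permutation tests for
    cell-type interaction enrichment, permutation-importance sensitivity
    scores per gene, latent-space domain detection, and a synthetic
    tissue generator with planted interaction structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    withr,
    igraph,
    e1071,
    class,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
biocViews: Transcriptomics, SingleCell, Spatial, Network, GraphAndNetwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
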