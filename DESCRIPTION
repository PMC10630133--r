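Package: scProto
Title: Single-Cell Integration with Learnable Condition Embeddings and
    Cell-Type Prototypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates single-cell count data (scRNA-seq or scATAC-seq
    fragment counts) across batches with a conditional variational
    autoencoder in which every batch condition is represented by a
    learnable continuous embedding rather than a one-hot indicator.
    Cell identities are modeled as latent-space prototypes used both for
    a supervised pull-in loss during fine-tuning and for nearest-prototype
    label transfer with distance-based uncertainty and unknown-cell
    detection. New (query) data are mapped onto a trained reference by
    learning only new condition embeddings with all network weights
    frozen. Sample-level analytics on the learned condition embeddings
    (PCA, covariate association via adjusted R-squared, kNN sample
    classification, gene-PC correlation screens) support multi-scale
    analysis across samples.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    SingleCellExperiment
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, ATACSeq, BatchEffect,
    Classification, DimensionReduction
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'data-io.R'
    'evaluation.R'
    'label-transfer.R'
    'likelihoods.R'
    'model.R'
    'nn-internal.R'
    'prototypes.R'
    'sample-space.R'
    'scProto-package.R'
    'synthetic.R'
    'training.R'
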