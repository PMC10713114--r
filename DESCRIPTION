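Package: cytopipe
Title: Flow and Mass Cytometry Processing, Normalization and Guided Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable, non-interactive workflow for flow and mass
    cytometry data: reading and writing FCS 3.0/3.1 files, channel
    subsetting and renaming, logicle/biexponential/arcsinh
    transformations, spillover compensation, landmark-based peak
    normalization across samples, declarative gating trees
    (rectangle, polygon, quadrant, interval), balanced non-destructive
    downsampling with percentile rescaling, cell-wise dataset
    splitting, UMAP embedding, a guided semi-supervised clustering
    method (hierarchical training, k-nearest-neighbour label
    propagation, threshold binarization and binary-proximity cluster
    collapsing), and downstream reporting: phenotype and abundance
    tables, sample-level embeddings with outlier flagging,
    nonparametric group comparisons and ROC analyses. Includes a
    synthetic-data generator producing multi-sample, multi-group
    datasets with known population structure, spillover and batch
    shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    FNN,
    uwot,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    cluster,
    withr,
    jsonlite
Config/testthat/edition: 3
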