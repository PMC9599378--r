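Package: ACAM
Title: Automatic Cell Type Annotation via Consensus Clustering and Marker
    Gene Importance
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates single-cell RNA-seq data without labelled training
    cells. Several clustering backends are run independently, the most
    mutually diverse are kept by adjusted-Rand-index variance, their
    co-clustering relations are intersected, and Louvain communities of the
    unanimous co-clustering graph larger than a size threshold become
    representative clusters. Each representative cluster is labelled by
    matching one-vs-rest gradient-boosted stump feature importances against
    a marker gene database, and remaining cells inherit labels from their
    nearest representative cell in a two-dimensional UMAP embedding.
    Includes a negative-binomial synthetic data generator with planted
    marker structure and the standard multiclass evaluation metrics.
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
    igraph,
    xgboost,
    uwot,
    Rtsne,
    mclust,
    cluster,
    FNN
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
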