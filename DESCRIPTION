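Package: wmclust
Title: M-Band Wavelet Multi-View Clustering of Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-view clustering of single-cell RNA-seq expression matrices
    via the orthogonal M-band discrete wavelet transform. A quality-controlled,
    log-normalized gene-by-cell matrix is decomposed along the gene axis into
    one approximation (trend) component and M-1 orthogonal detail components;
    each component is embedded with PCA, turned into a shared-nearest-neighbor
    graph, and clustered independently with Louvain community detection. The
    resulting multi-view partitions are assessed with marker-gene set
    intersection analysis (exclusive UpSet-style membership for every subset of
    views) and pairwise adjusted Rand index / normalized mutual information
    concordance. Includes a 10x Genomics MTX/CSV reader, the standard cell and
    gene quality-control filters, a seed-reproducible negative-binomial count
    simulator with planted major clusters, sub-clusters and QC violations, and
    a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    matrixStats,
    uwot,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    optparse,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
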