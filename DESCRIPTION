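Package: ecoregions
Title: Multithemed Ecological Regionalization by Spatially Constrained
    Spectral Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Delineates contiguous, homogeneous ecological regions from
    multi-theme geospatial feature tables over a spatial adjacency graph.
    Implements spatially constrained spectral clustering in which a Gaussian
    feature-similarity matrix is masked by a binary delta-neighborhood
    contiguity matrix (Hadamard product) before a generalized graph-Laplacian
    eigendecomposition and multi-restart k-means; companion methods include
    constraint-only spectral clustering, plain k-means and a random baseline.
    Provides evaluation metrics (within/between sums of squares, percent of
    must-link constraints preserved, region contiguity counts), selection of
    the number of regions against a random-clustering null via a windowed
    ratio-of-slope-changes statistic, random-forest Gini importance profiling
    of region drivers, variance partitioning of independent point responses
    across regions, and a synthetic-landscape generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
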