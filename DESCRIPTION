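Package: scamp
Title: Scalable Single-Cell Analysis with Annotated Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scalable toolkit for single-cell gene expression analysis
    built around an annotated observations-by-variables matrix container
    with optional HDF5 on-disk backing. Provides preprocessing (filtering,
    total-count normalization, highly variable gene selection, covariate
    regression, scaling, PCA), a k-nearest-neighbor graph engine based on
    blocked pairwise-distance computation, diffusion maps and diffusion
    pseudotime with branching detection, Louvain modularity clustering,
    marker-gene ranking, force-directed graph layout, simulation of single
    cells from boolean gene-regulatory networks via continuous Hill-function
    dynamics, synthetic fixture generators, and a command-line pipeline
    interface. Reads and writes its own HDF5 container, loom files, and
    10x-style MatrixMarket directories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    rhdf5,
    irlba,
    RSpectra,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'scamp-package.R'
    'AllGenerics.R'
    'utils.R'
    'AnnMatrix-class.R'
    'RcppExports.R'
    'preprocess.R'
    'fixtures.R'
    'grn.R'
    'rank-genes.R'
    'neighbors.R'
    'cluster.R'
    'trajectory.R'
    'io-h5am.R'
    'cli.R'
    'io-loom.R'
    'io-mtx.R'
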