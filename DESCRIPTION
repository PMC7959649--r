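Package: artomo
Title: Algebraic Reconstruction for Limited-Angle Tomography with
    Parallel-Block Solvers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Algebraic computed-tomography toolkit for incomplete
    (limited-angle) data. Builds sparse ray-driven system matrices for an
    opposite-walls (1 x 1) scanning geometry and for complete parallel-beam
    acquisitions, simulates piecewise-constant phantoms and their noiseless
    projections, and reconstructs by row-action methods: the Kaczmarz
    algorithm, ART with relaxation and a non-negativity constraining
    operator, and a parallel-block (PB) variant that sweeps disjoint row
    blocks from a shared iterate and recombines them with diagonal
    column-sum weighting matrices. Includes the max-absolute-pixel error
    metric, relaxation-parameter sweeps and block-scaling experiments, plus
    MatrixMarket/CSV/PGM import and export and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    jsonlite,
    Rcpp,
    stats,
    utils,
    parallel
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
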