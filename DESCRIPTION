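Package: scsc
Title: Simultaneous Coherent Structure Coloring for Unsupervised Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised clustering by amplifying pairwise dissimilarity.
    Builds a dissimilarity adjacency matrix from Lagrangian trajectory
    ensembles (normalized standard deviation of pair separation) or from
    row-stochastic transition matrices (square-root Jensen-Shannon
    divergence), solves the generalized graph-Laplacian eigenproblem
    L X = lambda D X, and converts the full descending eigenvector sequence
    into per-state binary codes and an occupancy dendrogram whose branch
    lengths are measured in units of the coloring merit z. Includes seeded
    benchmark generators: the unsteady quadruple-eddy ocean flow, the Bickley
    jet atmospheric flow (fifth-order Runge-Kutta advection, periodic
    east-west boundary), a uniform-noise control ensemble, and planted-block
    synthetic Markov state models with Ward-linkage (MVCA) coarse-graining
    for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
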