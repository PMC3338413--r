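Package: microfe
Title: Image-Based Micro-Finite-Element Analysis of Trabecular Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Linear elastic micro-finite-element (microFE) analysis of
    high-resolution bone images, where every voxel of a bone-volume-fraction
    map becomes one hexahedral element. Implements a matrix-free
    element-by-element stiffness operator with Jacobi-preconditioned conjugate
    gradients, a stress-based convergence estimator fitted to the iteration
    history, load-balanced slab partitioning of the solve, pre-iteration on
    coarser grids for warm starts, analytic memory/cost models for planning
    large runs, synthetic trabecular-structure generators, and readers/writers
    for NIfTI, MetaImage and raw volumes, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    optparse,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
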