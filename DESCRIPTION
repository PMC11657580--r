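Package: shapegrade
Title: Shape-Based Disease Grading with Functional Maps and Graph
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric classification of anatomical surfaces without
    point-to-point correspondence. Triangle meshes are compared through
    functional maps computed in truncated Laplace-Beltrami eigenbases of a
    regularized isophotic metric (first plus omega times third fundamental
    form), refined by ZoomOut and aligned collection-wide by a consistent
    latent basis. Area-based and conformal shape-difference descriptors are
    evaluated on the latent basis as symmetric positive-definite matrices,
    linearized in the Log-Euclidean framework, and classified transductively
    with a Chebyshev-polynomial graph convolutional network on a
    phenotype-gated population graph. Includes mesh I/O (OFF, PLY, OBJ), a
    synthetic cohort generator, and stratified Monte Carlo cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    pracma,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
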