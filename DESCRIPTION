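Package: ManifoldCapacity
Title: Mean-Field Classification Capacity and Anchor-Point Geometry of
    Neural Object Manifolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the linear classification capacity of object manifolds
    (labeled clouds of population-response vectors) with a replica mean-field
    estimator, extracts the anchor-point geometry of each manifold (effective
    radius and effective dimension), removes low-rank common components of
    manifold centers before analysis, and cross-validates the theory against a
    direct numerical measurement of linear separability by random projections
    and random dichotomies. Ships synthetic generators (random point clouds,
    balls, unbounded subspaces, smooth affine-warp image manifolds) so every
    component is testable without external activation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    data.table,
    withr,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, MathematicalBiology, Neuroscience
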