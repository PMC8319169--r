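Package: texpool
Title: Texture Statistics, Synthesis, and a Foveated Pooling Observer Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for parametric visual texture analysis and synthesis, and for
    simulating a physiologically inspired observer of peripheral vision. Images
    are decomposed with a complex steerable pyramid (a tight frame of oriented
    bandpass filters); pairwise-product summary statistics (spatial, cross-scale,
    cross-orientation and phase-doubled covariances) are measured either globally
    or as weighted averages within eccentricity-scaled, polar-separable pooling
    windows that tile the visual field. Texture families are synthesized from
    Gaussian white noise by iterative statistic matching; an AXB discrimination
    observer with per-statistic rescaling, global Euclidean-norm normalization
    and additive Gaussian noise predicts how texture family and texture sample
    discrimination change with stimulus size and eccentricity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    png,
    tiff,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
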