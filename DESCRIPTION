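Package: stocbct
Title: Spatiotemporally Optimized 4D Cone-Beam CT: Virtual Scanner, Adaptive
    Reconstruction and Image-Quality Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A virtual 4D cone-beam CT scanner for respiratory-correlated
    imaging research. Simulates a breathing thorax phantom and a chest-height
    surrogate signal, predicts respiratory phase in real time from an
    ellipse fitted to the lagged surrogate, and closes the loop with a
    gantry-speed/gating controller so that the acquired projections have an
    ideal interleaved angle/phase structure (spatiotemporal optimization).
    Includes a cone-beam forward/back projector with short-scan FDK and
    phase-resolved 4DFDK reconstruction, a McKinnon-Bates perturbation
    reconstruction, B-spline deformable registration with a Mattes mutual
    information metric, deformation-field inversion and motion-compensated
    adaptive reconstruction, plus schedule and image-quality metrics
    (mean absolute angular error, interbin angular separation,
    contrast-to-noise ratio, tissue interface width, dose-reduction
    bookkeeping and motion-model robustness).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    pracma,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
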