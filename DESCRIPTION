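Package: femload
Title: Micro-Finite-Element Based Inverse Remodelling Joint Load Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hip joint load vectors from trabecular bone
    architecture by inverse remodelling: voxel images are segmented and
    aligned into an implant-style anatomical frame, unit load cases are
    applied over sphere-cone contact patches, linear elastic voxel
    finite-element models are solved for per-element strain energy
    density, and non-negative least squares finds the load-case scaling
    that brings the tissue stimulus closest to remodelling equilibrium.
    Includes a forward-remodelling synthetic specimen generator, an
    OrthoLoad-style load-trace emulator, a one-at-a-time parameter
    sensitivity harness, and in-vivo-style plausibility comparison
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
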