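Package: gpsholo
Title: In-Line Phase-Shifting Digital Holography Simulation and Reconstruction
Version: 0.1.0
Authors@R:
    person("Plankton", "Imaging Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates in-line phase-shifting digital holograms of
    plankton-like amplitude objects, reconstructs the complex object wave
    from two interferograms with a two-step generalized phase-shifting
    algorithm, generates labeled synthetic hologram datasets with
    YOLO-format bounding boxes, trains a compact add-skip encoder-decoder
    network for single-frame hologram inversion, and scores object
    detection with precision/recall, PR curves and mAP. The scalar
    diffraction core uses an FFT transfer-function Fresnel propagator;
    the network (convolution, batch normalization, max pooling,
    transposed convolution, Adam) is implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
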