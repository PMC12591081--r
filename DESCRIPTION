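Package: pbct
Title: Propagation-Based Phase-Contrast CT Simulation and Quality Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and quantitative analysis of propagation-based
    phase-contrast computed tomography (PB-CT) of weakly absorbing,
    monomorphous (homogeneous, single-material-ratio) samples such as breast
    tissue. Provides Beer-Lambert/X-ray projection of voxelised phantoms,
    free-space propagation by the homogeneous transport-of-intensity equation
    (TIE-Hom) and by an angular-spectrum Fresnel propagator, single-distance
    TIE-Hom (Paganin-type) phase retrieval in two and three dimensions with
    matching real-space kernels, parallel-beam filtered back-projection
    reconstruction, and the noise-resolution-dose quality metrics Q_S and Q_C
    together with the theoretical signal-to-noise gain factors G1, G2 and G3
    of phase retrieval, including closed-form approximations for the
    three-dimensional gain and an analytic CT quality estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
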