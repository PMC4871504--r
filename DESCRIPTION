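Package: swarmsim
Title: Biologically Plausible Simulation and Statistical Evaluation of
    Flying-Insect Swarms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of flying-insect swarms using a force-based
    dynamics model (zonal repulsion/alignment/attraction interactions,
    quadratic air drag, stimulus pursuit/escape responses) combined with a
    spatially smooth stochastic force drawn from one of four noise fields
    (white, Gaussian white, Perlin gradient noise, divergence-free curl
    noise) and reciprocal-velocity-obstacle collision avoidance in 3D.
    Includes seven kinematic trajectory metrics, an entropy-weighted
    distributional similarity score between simulated and reference swarms,
    and a genetic-algorithm parameter estimator that calibrates the dynamics
    model against reference trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
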