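Package: skyclass
Title: Synthetic Flight Trajectories and Recurrent Classification of Birds
    Versus Drones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained testbed for trajectory-based discrimination of
    biological and mechanical flight. Simulates physically plausible 3-D
    trajectories of flying birds (pigeon, gull and peregrine presets, via a
    stochastic bank-angle/turn-rate kinematic model) and of a point-mass
    quadrotor under PID waypoint control, both embedded in a shared wind field
    with Ornstein-Uhlenbeck gusts and a thermal updraft. Provides a JSON
    trajectory interchange format, descriptive and biomechanical plausibility
    statistics, a pinhole-camera renderer for image-plane tracks, and a
    bidirectional LSTM (or GRU) sequence classifier trained with a masked
    binary cross-entropy on padded sequences, implemented natively with
    'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    png,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
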