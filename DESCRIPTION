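Package: fishcensus
Title: Agent-Based Simulation of Bias and Precision in Underwater Visual Census
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional agent-based simulator of diver-operated
    underwater visual census (UVC). Fish move by weighted steering ("urge")
    vectors with stochastic behavioural states and per-state detectability;
    divers run strip transects or rotating stationary point counts with a
    saturating, memory-based counting rule. Monte-Carlo sweeps over survey
    design parameters (transect length, width and swim speed; point-count
    radius, duration and rotation speed) quantify the bias and precision of
    density estimates for schooling, cryptic, shy and bold behavioural
    traits, including the overestimation caused by non-instantaneous
    sampling of mobile fish.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
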