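Package: confcircuit
Title: Attractor Decision Network with Adaptive Confidence Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a reduced mean-field attractor network for
    two-alternative perceptual decisions coupled to a pool of confidence
    neurons equipped with spike-frequency adaptation (or, alternatively,
    short-term synaptic depression). The confidence pool monitors the
    ramping activity of the decision circuit and its firing rate at
    decision time behaves like behavioural decision confidence: it
    predicts accuracy, shows the folded-X pattern across correct and
    error trials, and separates psychometric curves by confidence level.
    Provides a reaction-time trial simulator, session/sweep batching,
    behavioural-signature statistics, CSV/YAML persistence and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    optparse,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
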