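Package: snnprune
Title: Online Adaptive Weight Pruning for Unsupervised Spiking Neural
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a two-layer winner-take-all spiking neural network
    with conductance-based leaky integrate-and-fire neurons and triplet
    spike-timing-dependent plasticity, and prunes its plastic synapses
    online while training with thresholds that adapt over time and over
    neuron groups ranked by firing activity.  Includes Poisson rate
    coding of images, label assignment and rate-based classification,
    synaptic-operation and energy accounting with a figure of merit for
    choosing network connectivity, hardware-overhead estimates for the
    pruning unit, IDX/ubyte dataset readers, and a synthetic pattern
    generator for desk-scale experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
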