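Package: dynsyn
Title: Neural Network Models with Dynamic Synapses
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and mean-field analysis of neural networks with
    Tsodyks-Markram short-term synaptic plasticity. Provides the continuous
    and discrete dynamic-synapse models (depression and facilitation), a
    stochastic binary attractor network whose stored memories destabilize
    into switching "dynamical memories", the order-parameter mean-field map
    with phase diagrams, the zero-temperature storage-capacity solver, a
    bistable stochastic rate model of cortical up-down transitions with
    permanence-time statistics (exponential versus power-law), and a
    feed-forward stochastic-multiresonance experiment in which a spiking
    neuron with an adaptive threshold detects weak periodic signals through
    dynamic synapses. All experiments are seeded and reproducible, with
    tidy CSV/JSON outputs and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
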