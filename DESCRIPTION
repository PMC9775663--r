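Package: shuntsim
Title: Behavioral Simulation of a Conductance-Based Silicon Synapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A behavioral simulator of a subthreshold analog synapse circuit with a
    synaptic reversal potential, capable of shunting inhibition. Models the
    ring-oscillator transconductance stage (closed-form subthreshold inverter
    timing plus a numerical ODE oracle), a four-bit digital-to-analog input stage
    with a linear-charge/linear-discharge gate, smooth and oscillatory
    charge-packet output modes, single- and unidirectional-two-compartment
    leaky integrate-and-fire neuron configurations, adaptive rectangular
    spike-timing-dependent plasticity on four-bit efficacies, and an
    end-to-end spatiotemporal spike-pattern detection experiment with its
    inhomogeneous-Poisson stimulus generator and hit/false-alarm scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
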