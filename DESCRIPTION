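Package: aisgain
Title: Axon Initial Segment Location and the Dynamic-Gain Bandwidth of Spiking Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compartmental simulation and analysis pipeline for studying how the
    location of the axon initial segment (AIS) shapes the frequency-response
    bandwidth of spike initiation. Provides a ball-and-stick conductance-based
    neuron with a relocatable AIS, sinusoid-in-noise stimulation with
    Ornstein-Uhlenbeck background, circular-statistics estimation of the
    dynamic transfer gain (cutoff frequency, high-frequency power-law exponent,
    propagation delay), phase-plane action-potential onset metrics, reduction
    to an exponential integrate-and-fire point neuron via the dynamic
    current-voltage method, and a liquid-state-machine network experiment with
    short-term synaptic plasticity evaluating a delayed-XOR task.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    deSolve,
    knitr,
    rmarkdown
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
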