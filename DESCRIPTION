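Package: pfcwm
Title: Dopamine-Modulated Working Memory, Criticality, and E/I Balance
    in a Spiking Cortical Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a recurrent network of leaky integrate-and-fire
    neurons with Tsodyks-Markram short-term synaptic facilitation and
    depression, organised into item-selective excitatory populations as in
    attractor models of prefrontal working memory.  A dopamine D1
    activation level scales excitatory-to-excitatory and
    excitatory-to-inhibitory synaptic efficacies through a pair of shifted
    sigmoids, tracing a trajectory through the EE-EI synaptic-strength
    plane.  The package provides the simulation engine (Rcpp), working
    memory loading/updating protocols with stimulus-duration thresholds,
    neuronal-avalanche detection with power-law exponent and
    branching-parameter estimation, excitatory/inhibitory current-balance
    metrics, and synthetic ground-truth generators for validating every
    analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tools,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
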