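Package: msidev
Title: Developmental Simulation of Audiovisual Interactions and the Modality
    Switch Cost
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Firing-rate network simulator for the development of audiovisual
    interactions during a bisensory reaction-time task. A three-layer,
    five-unit network (auditory and visual input units, modality-specific
    inhibitory interneurons with slow feedback traces, and a multisensory
    output unit) is integrated with a compiled explicit-Euler core. Hebbian
    long-term potentiation of excitatory and cross-modal synapses and an
    anti-Hebbian rule for feedback inhibition drive a developmental training
    loop in which initially inhibitory cross-modal connections become
    excitatory, shifting the network from cross-modal competition to
    facilitation. Includes the six-condition repeat/switch trial battery with
    threshold-crossing reaction-time readout, typically-developing and
    autism-spectrum cohort experiments (reduced plasticity, reduced
    multisensory exposure, early and late multisensory interventions),
    trajectory comparison utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
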