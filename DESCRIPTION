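Package: thalamosim
Title: Desk-Scale Reconstruction and Simulation of a Thalamoreticular Microcircuit
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and simulates a biologically constrained microcircuit of the
    thalamic reticular nucleus (Rt) and the ventral posterolateral nucleus (VPL)
    of the mouse somatosensory thalamus. The pipeline generates synthetic neuron
    morphologies, places somata by Poisson-disc sampling in a hexagonal-prism
    volume, derives chemical and electrical connectivity from morphological
    appositions pruned against experimental bouton densities, equips connections
    with stochastic Tsodyks-Markram short-term plasticity and conductance-based
    receptor kinetics, and integrates reduced two-compartment bursting neuron
    models under wakefulness-, anesthesia- and slice-like protocols. Includes
    spike-train analysis utilities for burst detection and spindle-band
    oscillation statistics (frequency, duration, strength, recruitment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
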