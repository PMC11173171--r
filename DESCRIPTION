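Package: gridcan
Title: Spiking Continuous Attractor Network Model of Grid Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of a spiking continuous attractor
    network model of medial entorhinal cortex grid cells. Izhikevich
    neurons with type-specific parameters, Tsodyks-Markram short-term
    synaptic plasticity with conductance-based AMPA/NMDA/GABA-A/GABA-B
    receptor currents, center-surround inhibitory connectivity with
    preferred-direction offsets, conjunctive (speed-by-direction) and
    place-cell drive derived from animal or synthetic foraging
    trajectories, and a grid-cell physiology analysis suite: spatial
    rate maps, autocorrelograms, grid scores, field size and spacing,
    population spectral bands, and spike-phase coupling. Includes the
    parameter-robustness sweep protocol over neuron and synapse model
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
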