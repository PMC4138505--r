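Package: purksim
Title: Multi-Compartment Purkinje Neuron Simulator with Layered Calcium
    Dynamics and Electrogenic Sodium Pumping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conductance-based simulation of a 41-compartment cerebellar
    Purkinje neuron (one soma, 20 smooth and 20 spiny dendrite
    compartments). The model combines Hodgkin-Huxley somatic and dendritic
    currents, a 13-state Markov resurgent sodium channel, an electrogenic
    3:2 Na+/K+ pump with lagged intracellular sodium accumulation, and a
    layered intracellular calcium system with a floating set point and
    climbing-fiber-triggered switches. It reproduces the intrinsic trimodal
    firing pattern (tonic spiking, bursting, quiescence), climbing-fiber
    toggling between up and down states, and parallel-fiber gain control of
    the tonic firing rate. Includes climbing-fiber and parallel-fiber
    synapse trains, named experiment protocols, and a spike-train analysis
    layer (spike and complex-spike detection, mode segmentation, toggle
    statistics). The integration core is written in C++ (backward-Euler
    cable solve, exponential-Euler gating, implicit Markov stepping at a
    25 microsecond time step).
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
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
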