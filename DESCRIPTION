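Package: beeAL
Title: Biophysical Model of Olfactory Learning in the Honeybee Antennal Lobe
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conductance-based network model of the honeybee antennal lobe
    (AL): Hodgkin-Huxley projection neurons and local interneurons, fast
    GABA-A, slow G-protein-coupled inhibition and nicotinic cholinergic
    synapses, and spike-triggered facilitation of inhibitory synapses
    (associative presynaptic and nonassociative postsynaptic modes with slow
    exponential forgetting). Includes percept-structured odor stimuli
    (simple classes, chemical-proportion blends, sensor-feature pulses),
    training protocols (differential, absolute, single-mode), two-environment
    relearning experiments, representation analyses (binned-count
    correlations, PCA trajectories, uniqueness index, contrast-enhancement
    regression), and a graph-convolutional-network analog of the circuit.
    The time-stepping core is a fourth-order Runge-Kutta integrator written
    in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
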