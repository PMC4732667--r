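Package: swimnet
Title: Conductance-Based Simulation of Electrically Coupled Rhythm-Generating Neuron Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates small populations of electrically coupled, conductance-based
    neurons with mutual glutamatergic (NMDAR/AMPAR) feedback excitation, modelled on
    the hindbrain descending interneurons (dINs) that drive swimming in the hatchling
    Xenopus tadpole. Provides Hodgkin-Huxley-type channel models and a
    Goldman-Hodgkin-Katz calcium current, dual-exponential event-driven synapses with
    voltage-dependent magnesium block of the NMDA receptor, gap-junction coupling,
    generative sensory (trigeminal interneuron) and inhibitory stop (mid-hindbrain
    reticulospinal) input pathways, a fixed-step implicit integrator, spike-train
    analysis utilities, and drivers for five in-silico experiments: NMDA perfusion,
    NMDAR summation, sensory start, inhibitory stop, and generalisation to generic
    Hodgkin-Huxley populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
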