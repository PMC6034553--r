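Package: pyrcable
Title: Compartmental Cable Models of Cortical Pyramidal Neurons, from Spines to Spikes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Passive and active compartmental modelling of cortical pyramidal
    neurons on SWC morphologies. Implements spine-area corrected passive cable
    models with an implicit tree-ordered (Hines) solver, two-state kinetic
    AMPA/NMDA synapses with Jahr-Stevens magnesium block, explicit
    two-compartment dendritic spine models, Rall shape-index localisation and
    conductance fitting of connected-pair EPSPs, two-stage NMDA-kinetics
    fitting, dendritic NMDA-spike detection and independent-subunit counting,
    multi-objective evolutionary fitting of somatic/axonal spiking models from
    spike-train features, synapse-count-to-somatic-spike probability curves,
    and one-/two-layer storage-capacity estimates. Ships seedable synthetic
    generators for morphologies, spine geometries, EPSP recordings and spike
    trains so every analysis stage can be exercised closed-loop against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
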