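Package: MFEsim
Title: Multiple-Firing-Event Dynamics in a Clustered Model of Primary Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a network model of layer 2/3
    of primary visual cortex built from conductance-based integrate-and-fire
    neurons arranged in hypercolumns and orientation domains. Fast (AMPA/GABA-A
    type) synapses are taken in the instantaneous limit, which makes population
    spike barrages -- multiple-firing events (MFEs) -- well defined single-instant
    cascades; the package resolves these cascades exactly with an event-driven
    closed-form algorithm, generates inhomogeneous Poisson feedforward drive
    (background plus drifting-grating stimulus), and provides the accompanying
    statistics: binomial 95th-percentile MFE detection, MFE/non-MFE spike
    decomposition, population cross-covariance, spike-triggered voltage
    distributions, LFP-proxy power spectra, trial-to-trial variability, and
    scripted benchmark protocols (correlated background activity, iso-oriented
    surround suppression, contrast-size interaction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
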