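Package: hdinephys
Title: Simulation and Analysis of Patch-Clamp Recordings from Stem
    Cell-Derived Interneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the in-silico analysis of whole-cell patch-clamp
    experiments on human stem cell-derived GABAergic interneurons (hdINs).
    Implements template-matching detection of spontaneous postsynaptic
    currents with 20-80 percent kinetics and amplitude/kinetics exclusion
    rules, intrinsic-property extraction (resting membrane potential,
    series/input resistance, action-potential features, sodium/potassium
    current-voltage curves with leak subtraction), optogenetic response
    analysis (photocurrent characterisation, first-event latency histograms
    and a Poisson bin test), nonparametric pharmacology statistics,
    cell-composition and delta-Ct arithmetic, plus ground-truthed synthetic
    session generators (Poisson postsynaptic-current trains, an adaptive
    exponential integrate-and-fire neuron, Boltzmann-gated conductances and
    channelrhodopsin photocurrents) so every analysis stage can be validated
    against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate:
    'utils.R'
    'AllClasses.R'
    'ephys_io.R'
    'kernel.R'
    'detect.R'
    'hdinephys-package.R'
    'intrinsic.R'
    'opto.R'
    'simulate_psc.R'
    'stats.R'
    'pipeline.R'
    'simulate_neuron.R'
    'simulate_opto.R'
    'simulate_tables.R'
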