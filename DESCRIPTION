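Package: cflnet
Title: Constrained Fuzzy Logic Modeling of Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains constrained fuzzy logic (cFL) models of signal
    transduction against perturbation-response data. Starting from a signed
    directed prior knowledge network (SIF) and normalized measurements in a
    MIDAS-dialect CSV, the package compresses the network against the
    experimental design, expands it into a hypothesis space of AND/OR gates
    with normalized-Hill or linear transfer functions, trains an ensemble of
    models with a discrete genetic algorithm, then reduces, refines and
    filters the family at user-set thresholds. Ensemble analysis covers gate
    frequencies and sensitivities, mean/SD/CV predictions, response surfaces,
    cross-validation and randomization-based significance. A synthetic-data
    module generates networks, ground-truth models, in-silico datasets and
    null controls for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
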