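Package: popsignal
Title: Low-Dimensional Read-Out of Parallel Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the read-out of parallel spike trains by a downstream
    neuron. Per-neuron decoding weights are learned from z-scored spike
    counts with a cross-validated soft-margin linear support vector machine
    (or a univariate ROC-based statistic), and single-trial spiking activity
    is collapsed into a one-dimensional population signal by weighting
    spikes and filtering with a causal exponential kernel. Includes
    permutation and weight-perturbation null models, sign- and layer-based
    subpopulation decompositions with size-correction factors, normalized
    cross-correlation functions between simultaneous population signals,
    current source density analysis of laminar field potentials for
    assigning units to cortical layers, and a synthetic session generator
    with planted, recoverable structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
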