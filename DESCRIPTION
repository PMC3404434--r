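Package: spikeinvar
Title: Transformation-Invariant Learning in Conductance-Based Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-layer network of conductance-based leaky
    integrate-and-fire neurons whose feed-forward synapses self-organize
    through multiplicative spike-timing-dependent plasticity (STDP).
    Translating-block stimuli with controlled spatial overlap are presented
    under sequential, interleaved or randomized schedules, so that
    translation-invariant stimulus representations can emerge through either
    continuous-transformation (spatial-overlap) or trace (temporal-continuity)
    learning. Performance is quantified with stimulus-specific single-cell
    information and a multiple-cell measure based on Gaussian-Bayesian
    decoding. The per-step dynamics are implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
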