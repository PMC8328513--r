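Package: stimcon
Title: Oscillating Network Model of Predictive Speech Timing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and analysis tools for STiMCON, a threshold-gated
    oscillating network model of speech tracking in which word-node
    activation sums bottom-up sensory evidence, top-down feedback weighted by
    an internal language model, a time-since-activation inhibition gate, and
    a fixed sinusoidal excitability drive. Includes stimulus constructors,
    processing-efficiency maps and timing-compression ratios, rhythmicity
    analysis of responses to pseudo-rhythmic input, the closed-form
    predictability-to-time-shift transform with onset-train spectral
    statistics, and grid-search fitting of the model to phase-dependent
    syllable-categorization curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
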