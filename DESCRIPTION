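Package: consensusconf
Title: Consensus Decision-Making and Confidence in Coupled Attractor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates perceptual decisions made collectively by a population of
    loosely coupled attractor modules that integrate a shared flickering-luminance
    stimulus under independent Ornstein-Uhlenbeck background noise. Each module
    votes for an option when a firing-rate threshold is crossed; the network
    commits when a strict majority agrees, and decision confidence is decoded
    from the inter-module dispersion of the chosen option's firing rates, or
    from its neural proxy, the fraction of modules counted just above threshold.
    Provides the stimulus generators and pulse protocols of the flicker
    brightness-discrimination task, reverse-correlation decision and confidence
    kernels, experiment drivers (coupling sweeps, pulse asymmetry, fixed-delay
    forced choice), a synthetic-subject generator, and a two-stage behavioral
    fitting pipeline (input gain/bias, then confidence sigmoid) driven by a
    covariance matrix adaptation evolution strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    rlang,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    readr
Config/testthat/edition: 3
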