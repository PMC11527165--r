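Package: insightnet
Title: Insight-Like Strategy Switches in Gated, Regularised Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates minimal gated linear networks (and a 48-unit ReLU
    hidden-layer variant) trained by noisy online stochastic gradient descent
    on a two-feature perceptual decision task in which a colour feature
    becomes predictive of the correct choice only late in training. Provides
    the task/curriculum generator with per-subject accuracy matching of
    motion-input means, the closed-form accuracy of the gated linear readout,
    and a behavioural insight-classification pipeline: binned accuracy series,
    linear/step/sigmoid switch-model fits compared by BIC, slope-at-inflection
    steepness with a goodness-of-fit correction, and control-cohort
    percentile thresholding. Cohort-level experiments cover matched 99-network
    samples with controls, gradient-noise and regularisation-strength sweeps,
    a weight-intervention experiment, and switch-locked gradient and
    change-point analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
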