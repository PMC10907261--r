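Package: empathylearn
Title: Observational Reinforcement Learning Models of Empathy Transmission
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and computational-modeling toolkit for the
    observational-learning-of-empathy paradigm. Generates synthetic cohorts
    with known ground truth (trial schedules, algorithmic demonstrator
    ratings, Rescorla-Wagner observers with discounted prediction-error
    empathy updating), fits the Rescorla-Wagner model and a family of
    discounted prediction-error models of empathy ratings by maximum a
    posteriori estimation, computes Laplace approximations to the model
    evidence, performs random-effects Bayesian model selection with
    exceedance probabilities, and provides model-independent behavioral
    statistics plus parameter- and model-recovery harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
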