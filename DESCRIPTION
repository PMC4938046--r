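Package: socialforage
Title: Evolution of Social Learning Under Resource Variance and Analysis of
    Bee Choice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based stochastic simulation of foraging populations in
    which individual learners sample patch profitability directly while
    social learners observe conspecifics, patch resources are shared
    equally among occupants (exploitative competition), and the learning
    strategy evolves by death and fitness-proportional replacement.
    Replicated experiments contrast no-variance worlds (resources spread
    equally over patches) with high-variance worlds (resources concentrated
    in few patches and periodically redistributed) and report the evolved
    proportion of social learners. A companion analysis pipeline for
    two-by-two bee choice experiments provides exact binomial tests against
    a chance landing level, adjusted-Wald (Agresti-Coull) confidence
    intervals, random-intercept logistic regression via 'lme4', first-k
    landing summaries, and a synthetic choice-data generator for testing
    the pipeline by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
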