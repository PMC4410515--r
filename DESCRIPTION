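Package: abductr
Title: Explanationist Probabilistic Belief Updating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying probabilistic but non-Bayesian belief updating,
    in which the hypothesis that best explains the evidence receives a bonus
    before renormalization. Implements probabilistic measures of explanatory
    power (the simple difference, Popper's ratio, Good's log-ratio with its
    bounded rescalings, and the Schupbach-Sprenger posterior-contrast measure),
    Bayesian and abductive updating over finite hypothesis partitions, the
    two-urn drawing experiment (draw likelihoods without replacement, objective
    posterior trajectories, per-draw explanatory-power scores), a synthetic
    generator for participant credence data with the linear structure assumed
    by the original regression analysis, maximum-likelihood linear model
    comparison (AIC, likelihood-ratio tests, Vuong's and Clarke's non-nested
    tests), and a coin-bias simulation comparing update rules on convergence
    speed and Brier-score inaccuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
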