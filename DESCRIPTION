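Package: repgame
Title: Active-Inference Simulation of a Donate/Keep Reputation Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-state active-inference agent for a donate/keep
    "reputation game" used in computational psychiatry to model the
    psychopathic traits "lacks remorse" and "self-aggrandizing" as aberrant
    precision. Builds the generative model (likelihood, transition, preference
    and prior structures) over joint wealth x self-worth states, performs
    exact Bayesian belief filtering and expected-free-energy policy selection,
    simulates complete games against a veridical environment, sweeps the
    likelihood precision (alpha) and transition-prior precision (beta) to map
    self-worth and wealth outcomes, and runs a staged developmental-trajectory
    scenario. Also provides the closed-form precision-weighted Gaussian
    self-appraisal model with undefended, self-aggrandizing and lacks-remorse
    presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
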