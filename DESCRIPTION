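Package: twostepr
Title: Simulation and Analysis of the Deterministic-Transition Two-Step Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying the balance between model-based and model-free
    reinforcement learning in the deterministic-transition two-step task.
    Provides a task simulator with bounded Gaussian random-walk payoffs, a
    hybrid SARSA(lambda) / Bellman learner with softmax choice and
    perseveration, synthetic cohort generation with known ground truth,
    per-session maximum a posteriori model fitting under empirical priors,
    stay-probability and repeated-measures behavioural statistics, the
    trial-level multilevel logistic stay regression yielding model-based and
    model-free indices, and a reproducible end-to-end analysis pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
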