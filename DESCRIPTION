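Package: reliefrl
Title: Reinforcement Learning and Drift Diffusion Modelling of Endogenous
    Pain Relief Modulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing probabilistic pain-relief gambling
    ("wheel of fortune") experiments in which wins deliver relief and
    losses deliver increases of a tonic painful heat stimulus. Implements
    a family of four reinforcement-learning drift-diffusion models
    (dual learning rates, optional scaled outcome sensitivity, linear or
    sigmoid value-to-drift mapping) with a Wiener first-passage-time
    likelihood over choices and reaction times, hierarchical Bayesian
    estimation across subjects and drug conditions with a non-centered
    parameterization, K-fold cross-validated ELPD model comparison,
    posterior predictive checks of choice proportions, trial-wise
    prediction-error extraction, and mixed-effects models linking
    prediction errors to trial-wise endogenous pain modulation. A
    synthetic-cohort generator simulates the full task so every stage of
    the pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
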