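Package: smfm
Title: Stochastic Mechanism-Fitting Models for Learning in Animal Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying social and asocial learning mechanisms
    from time-structured records of group diffusion experiments. Individual
    rates of interaction with a two-option, two-box foraging task are
    modelled in continuous time as a function of Rescorla-Wagner
    reinforcement state, permanent observational learning, and transient
    social-enhancement kernels (general, box-level, stimulus and specific
    local enhancement) that decay exponentially after an observation.
    Includes an exact event-history likelihood, adaptive-Metropolis MCMC
    with highest-posterior-density summaries and DIC model comparison, Cox
    proportional-hazards analyses of within-bout solving and abandonment
    with all-subsets AIC model averaging, a randomization test for
    group-level option biases (traditions), and a forward simulator of
    seeded diffusion experiments for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
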