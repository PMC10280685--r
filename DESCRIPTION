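Package: jirt
Title: Bayesian Joint Modeling of Response Accuracy and Response Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hierarchical Bayesian joint models for item response
    accuracy and response times. A normal-ogive (probit) item response
    model describes the binary accuracy data and a log-normal model
    describes the response times; person parameters (ability, working
    speed) and item parameters (discrimination, difficulty, time
    discrimination, time intensity) are linked through multivariate
    normal population distributions with conjugate normal-inverse-Wishart
    hyperpriors. Estimation is by data-augmentation Gibbs sampling with
    built-in identification handling, optional guessing, explanatory
    variables, missing-at-random imputation and missing-by-design masks.
    Includes Bayesian person-fit, item-fit and residual diagnostics, a
    differential working-speed (latent growth) extension, chain
    diagnostics (effective sample size, Monte Carlo standard errors) and
    a synthetic-data generator for simulation studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
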