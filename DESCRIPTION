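Package: dtcox
Title: Robust Inverse Probability Weighted Cox Regression for Doubly
    Truncated Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of doubly truncated event times, where a
    subject is observed only if its event time falls inside a random interval.
    Implements the nonparametric maximum likelihood estimator (NPMLE) of the
    event-time distribution and selection probabilities via the EM algorithm,
    closed-form plug-in influence-function matrices for the NPMLE, inverse
    probability weighted Cox regression with time-varying weights (including
    robust survival-function weights) and closed-form sandwich standard
    errors, an inverse probability weighted Breslow baseline hazard with
    influence-function confidence intervals, sensitivity analysis for
    violations of the positivity assumption based on a modified at-risk
    process, nonparametric diagnostics for quasi-independent truncation and
    ignorable sampling bias, and a simulation engine for validating the
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
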