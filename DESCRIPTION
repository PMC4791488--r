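Package: ppestim
Title: Parametric Power Estimation for Mixed-Effects Model Hypothesis Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Power and sample-size analysis for likelihood-ratio and Wald tests
    in (non-linear) mixed-effects models via parametric power estimation (PPE):
    the non-centrality parameter of the test statistic's distribution under the
    alternative hypothesis is estimated by maximum likelihood from a modest
    number of Monte Carlo simulation-estimation replicates, converted to power
    through the non-central chi-square distribution, and scaled linearly with
    study size to yield full power-versus-sample-size curves. Includes a
    parametric bootstrap for Monte Carlo uncertainty, an empirical-CDF band
    diagnostic for the distributional assumption, a reference Monte Carlo power
    estimator (MCPE), a compact simulate-estimate engine for binary,
    time-to-event, count and Gaussian-linear mixed-effects models, and an
    evaluation harness comparing the two estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
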