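Package: ncdproj
Title: Premature NCD Mortality Projection and Risk-Factor Scenario Analysis
Version: 1.0.0
Authors@R:
    person("ncdproj", "developers", email = "ncdproj@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative-risk scenario analysis of premature
    mortality from non-communicable diseases (NCDs). Computes the
    unconditional probability of dying between exact ages 30 and 70 (40q30)
    from cause-specific death rates, projects it together with six modifiable
    risk-factor exposures to a horizon year using Bayesian model averaging,
    spatiotemporal interpolation and Gaussian-process smoothing, derives
    population attributable and potential impact fractions with theoretical
    minimum risk exposure levels, estimates avoidable deaths under WHO-target
    and counterfactual scenarios, classifies SDG 3.4 achievement (one-third
    reduction) by sex and sub-national unit, and quantifies life-expectancy
    gains with cause-deleted life tables. A synthetic-data module generates
    registry-style mortality and survey-style exposure inputs with known
    ground truth so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
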