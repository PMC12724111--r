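Package: trialcea
Title: Within-Trial Cost-Effectiveness Analysis with Bootstrapped
    Acceptability Curves and Multiple Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for within-trial economic evaluation of randomised
    controlled trials: micro-costing of complex interventions (staff time,
    indirect-activity ratios, supervision and amortised training), pricing of
    participant service-use records against a unit-cost table, quality-adjusted
    life years from utility trajectories by trapezoidal area under the curve,
    covariate-adjusted between-arm differences from mixed-effects linear
    regression with a recruiting-site random intercept, incremental
    cost-effectiveness ratios, net monetary benefit, non-parametric bootstrap
    of joint incremental cost-effect distributions, cost-effectiveness
    acceptability curves over willingness-to-pay grids, and sensitivity
    analyses via chained-equation multiple imputation with predictive mean
    matching and Rubin's rules. Includes a calibrated synthetic-trial
    generator so the full pipeline can be exercised and validated without
    access to confidential participant-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
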