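Package: trialecon
Title: Trial-Based Economic Evaluation of Return-to-Work Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, effectiveness analysis, and societal-perspective
    economic evaluation of three-arm randomized return-to-work trials for
    workers on sick leave. Provides a synthetic cohort generator with a
    monthly work-status panel, sustained return-to-work survival outcomes,
    robust and mixed-effect outcome models, multiple imputation by chained
    equations with predictive mean matching and Rubin's-rules pooling,
    micro-costing and human-capital valuation of productivity losses,
    seemingly unrelated regression of costs and effects, bootstrap
    incremental cost-effectiveness ratios, cost-effectiveness planes and
    acceptability curves, and return-on-investment metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    survival,
    lme4,
    nlme,
    sandwich,
    lmtest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
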