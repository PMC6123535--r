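Package: indicer
Title: Individualized Cost-Effectiveness Analysis for Two-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts six-month quality-adjusted life years (QALYs) and
    societal costs per treatment arm from baseline characteristics of a
    two-arm depression trial (treatment as usual versus blended treatment),
    and turns the per-patient predictions into individual treatment
    recommendations via the incremental cost-effectiveness ratio and a
    willingness-to-pay threshold on the cost-effectiveness plane. Includes
    a synthetic trial generator with known ground-truth potential outcomes,
    EQ-5D-5L utility valuation and trapezoidal QALY integration, societal
    costing from resource use, a suite of per-arm outcome/cost learners
    evaluated by leave-one-out cross-validation against a mean reference,
    lasso feature selection, and counterfactual evaluation of the
    recommended allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    rpart,
    e1071,
    jsonlite,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
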