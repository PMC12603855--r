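Package: schcea
Title: Cost-Effectiveness Analysis of Remote Symptom-Monitoring Intervention Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A weekly-cycle Markov cohort model of unplanned health-care
    utilization (emergency-department visits and unplanned hospitalizations)
    for the five arms of a randomized component evaluation of the Symptom
    Care at Home (SCH) electronic patient-reported outcome system.
    Implements a synthetic patient-level trial generator, calibration of
    utilization and symptom-burden inputs from patient records,
    deterministic and microsimulation cost engines, incremental
    cost-effectiveness and dominance-frontier analysis, second-order
    probabilistic sensitivity analysis with beta/gamma parameter draws, and
    cost-effectiveness acceptability curves over willingness-to-pay
    thresholds expressed per 1-point reduction in symptom burden.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
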