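Package: cgmscreen
Title: Prediabetes Screening from Continuous Glucose Monitoring Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for screening prediabetes from flash continuous glucose
    monitoring (CGM) data. Parses canonical and Libre-style CGM exports,
    trims sensor warm-up periods, and computes duration-weighted glycemic
    variability features (mean, spread, MAGE, time-in-range, excursion rise
    and fall statistics) on irregular time series. Assigns glycemic status
    from fasting glucose, 2-hour OGTT glucose and HbA1c using ADA criteria,
    fits logistic-regression and support-vector-machine classifiers on
    nested predictor sets, and evaluates a 2-step HbA1c-stratified screening
    strategy against the plain HbA1c >= 5.7 percent rule using repeated
    random-subsampling validation with ROC and precision-recall summaries.
    Includes a calibrated synthetic cohort generator (linked demographics,
    clinical glycemia and CGM traces) so the full pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
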