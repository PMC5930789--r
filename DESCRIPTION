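Package: m1claims
Title: Case-Finding Algorithms for Metastatic Gastric Cancer in Administrative Health Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build, apply and validate administrative-data algorithms that
    identify metastatic (M1) gastric cancer when registry TNM stage is unavailable.
    Implements three tiers of ICD-9/ICD-10 metastasis code lists with prefix matching,
    twenty-seven case-finding rules crossing code tier, record source (hospitalization
    and outpatient thresholds) and peri-diagnosis time window, diagnostic accuracy
    evaluation against a chart-review reference standard (sensitivity, specificity,
    predictive values and accuracy with percentile-bootstrap confidence intervals),
    discordance profiling and a content-validity mortality comparison. A synthetic
    linked-claims cohort simulator with a closed-form performance oracle supports
    calibration and end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
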