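Package: ddcea
Title: Cost-Effectiveness of D-Dimer Cut-Off Strategies for Ruling Out
    Venous Thromboembolism in Cancer Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evaluates diagnostic D-dimer rule-out strategies (fixed,
    age-adjusted, inverse age-adjusted, and data-derived cut-offs) for
    suspected venous thromboembolism in cancer patients.  Provides a
    seeded synthetic cohort generator calibrated to age-stratified
    median/IQR summaries with exact sub-threshold count constraints,
    threshold decision rules, diagnostic performance statistics
    including nonparametric AUC with DeLong confidence intervals, and a
    dual-currency cost-minimization model of avoided imaging with
    annual extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
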