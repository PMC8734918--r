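Package: trialops
Title: Multisite Clinical Trial Operations: Accrual Analytics, Randomization, Reporting and Data Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tooling for running the operational side of a multisite randomized
    clinical trial: windowed accrual summaries and a Gini index of accrual
    inequality across sites, Bayesian posterior-predictive forecasting of the
    enrollment completion date under a Poisson-gamma accrual model, stratified
    table-driven treatment randomization with adaptively appended schedules,
    a scheduled operational report suite (accrual, pharmacy resupply, delivery
    watch list, adverse events, investigator sign-off, data queries), an
    edit/logic/range check engine with an open-sent-resolved query lifecycle
    and dataset-lock gate, and a trial simulator that generates complete
    synthetic multisite datasets (with an error-injection answer key) so every
    component is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
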