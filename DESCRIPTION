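Package: beta2hr
Title: Sensor-Based Analysis of Inhaled Beta-2 Agonist Effects on Heart Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the heart-rate side effects of inhaled beta-2
    agonists from minute-resolution wearable data and smart-inhaler actuation
    logs. Provides a cohort-level comparison of heart rate by long-acting
    beta-2 agonist (LABA) status using patient-first hourly averaging, and a
    self-controlled event study around short-acting beta-2 agonist (SABA)
    inhalations with clock-time-matched control days, a step-count activity
    filter, and threshold-crossing summaries of the resulting difference
    curve. A synthetic wearable-cohort generator with circadian heart-rate
    rhythm, activity bouts, parametric drug-effect kernels, inhaler schedules
    and wear gaps makes every pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
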