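Package: htnrms
Title: Rule Engine for Remote Hypertension Management Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, auditable implementation of a remote
    hypertension management clinical algorithm of the kind run under
    collaborative drug therapy management (CDTM) agreements: program
    eligibility screening with an orthostatic-hypotension postural test,
    home blood-pressure telemonitoring aggregation with per-channel
    outlier exclusion and sufficiency grading, daily critical-value
    alerting over rolling 7-day windows, alarm-symptom triage,
    laboratory gating of prescribing by drug class, and a
    medication-titration state machine covering pathway assignment,
    dose escalation with lockouts, fourth-line logic, secondary-cause
    screening and referral. Every threshold is read from a shipped,
    editable configuration. A seeded synthetic-cohort simulator closes
    the loop so the full program can be exercised end to end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
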