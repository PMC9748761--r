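# htnrms

A deterministic, auditable R implementation of a remote hypertension
management clinical algorithm — the kind of pharmacist-run protocol used
under collaborative drug therapy management (CDTM) agreements, where
patients transmit scheduled home blood-pressure readings and medication
changes are made algorithmically between office visits.

It is written for digital-health and clinical-informatics teams who need
the decision logic of such a program as testable code: every rule is a
pure function of its declared inputs, every threshold lives in an
editable configuration file, and a seeded synthetic-cohort simulator
exercises the whole closed loop without patient data.

## What the engine implements

* **Eligibility screening** — office-BP inclusion rules (most recent
  office SBP ≥ 135 or DBP ≥ 85 mmHg within 6 months, or the mean of the
  three most recent readings within 18 months crossing 135/85) and coded
  exclusions (age band 26–80, 40+ with diabetes; pregnancy; HFrEF;
  severe aortic stenosis; bilateral renal artery stenosis;
  eGFR < 30 ml/min/1.73 m²; orthostatic hypotension by a ≥ 20/≥ 10 mmHg
  postural drop; cuff-fit weight limits; a controlled 24-h ABPM).
* **Home-BP aggregation** — twice-daily duplicate measurement schedules
  (7 days/28 readings optimal, 3 days/12 minimal), weekly per-channel
  means with single-pass exclusion of values more than 3 SD from the
  weekly mean, sufficiency grading, and goal classification against
  130/80 mmHg (135/85 with frailty).
* **Safety alerts** — daily scanning of a trailing 7-day window for
  SBP ≤ 90, DBP ≥ 120, SBP ≥ 200 on any one day, 2 days of SBP ≥ 190 or
  3 days of SBP ≥ 180; recheck-in-1-hour patient instructions; and a
  closed alarm-symptom list routed to EMS.
* **Lab gating** — per-class blocks (ARB/ACEI: K ≥ 5.2 mmol/L,
  eGFR < 30, eGFR drop ≥ 30% from baseline; thiazides: K < 3.5 or
  Na < 135; MRA additionally a conservative-dose band for
  4.5 < K < 5.2), advisory warnings, post-titration draw windows
  (1–2 weeks; final dose within 4 weeks; every-other-titration cadence
  on ≥ 3-step ladders), and repeat-or-down-titrate triggers
  (creatinine rise ≥ 30%; K rise ≥ 15% *and* K > 5).
* **Titration state machine** — pathway assignment (CCB-first standard;
  ARB/ACEI-first for diabetes, eGFR < 60 or UACR ≥ 30 mg/g;
  CCB-then-labetalol for women of childbearing potential), one
  recommendation per weekly report in a fixed priority order:
  at-goal hold → safety-floor/low-heart-rate physician conversation →
  titration lockout (1 week; 6 weeks for MRA) → lifestyle-first trial →
  maximize-before-add sequencing → HCTZ-to-chlorthalidone switch within
  10 mmHg of goal → secondary-cause screen → MRA or beta-blocker fourth
  line → specialist referral. A pandemic mode substitutes lab-free
  classes (CCB, then labetalol) when blood work is unavailable.
* **Simulator** — a seeded cohort generator with a linear dose-step
  response model, measurement noise, office white-coat offsets and
  drug-induced lab shifts, driving the full weekly loop
  (`run_program()`).

All numeric constants above are read from
`inst/extdata/default_config.yaml`, never hard-coded; the dose ladders
there are editable site defaults.

## Worked example

A 58-year-old man with diabetes (RAAS-first pathway), one week of home
readings containing a spurious 230 mmHg transmission, already on
irbesartan 150 mg:

```r
library(htnrms)

profile  <- patient_profile("pt-042", age = 58, sex = "male", diabetes = TRUE,
                            ascvd_risk_10yr = 0.18, medication_naive = FALSE)
baseline <- lab_panel("2021-12-15", k = 4.1, na = 140, creatinine = 1.0,
                      egfr = 72, uacr = 45, role = "baseline")
assign_pathway(profile, baseline)$pathway
#> [1] "RAAS_FIRST"

bp <- bp_stream(
  timestamp = paste(rep(seq(as.Date("2022-01-03"), by = 1, length.out = 7),
                        each = 4),
                    c("07:30:00", "07:32:00", "19:30:00", "19:32:00")),
  sbp = c(rep(148, 27), 230), dbp = 92, hr = 74)
(summary <- weekly_average(bp, window_start = "2022-01-03"))
#> <weekly BP> 2022-01-03: 28 readings/7 days [optimal] mean 148.0/92.0 (excl 1/0)

goal <- goal_status(summary, frail = FALSE)
regimen <- list(medication_state("irbesartan", dose_step = 2,
                                 start_date = "2021-12-20"))
next_action(profile, pathway = assign_pathway(profile, baseline), regimen,
            summary, goal, labs = baseline, baseline_labs = baseline,
            as_of = as.Date("2022-01-10"))
#> <recommendation> TITRATE irbesartan -> step 3 [lab gate]
#>   rationale: BELOW_MAX_TITRATE, PATHWAY_RAAS_FIRST
```

The 230 mmHg artifact is excluded (it lies more than 3 SD from the
weekly mean), leaving a weekly average of 148/92 — above the 130/80
goal — so the engine escalates the current agent one step. The
recommendation is flagged `[lab gate]`: prescribing is conditional on
`check_gate("ARB", latest, baseline)` passing (here: K < 5.2, eGFR ≥ 30,
no ≥ 30% eGFR drop).

A shell surface over the same functions is available at
`inst/cli/htn-rms.R` (`screen`, `weekly-report`, `alerts`, `lab-gate`,
`recommend`, `simulate`).

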