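# Default program configuration.
#
# Every numeric rule threshold used anywhere in the engine resolves through
# `thresholds:`; none is hard-coded in logic.  Dose sequences under
# `dosing_table:` are editorial defaults seeded from the in-protocol
# sequences (irbesartan 75/150/300 mg; HCTZ 12.5/25 mg with chlorthalidone
# 25 mg as the thiazide up-titration; spironolactone 12.5/25/50 mg); steps
# for the remaining agents are conventional outpatient sequences and are
# meant to be replaced by a site's own dosing appendix without code changes.

thresholds:
  # BP goals (mmHg); frail goals are deliberately more permissive
  goal_sbp_standard: 130
  goal_dbp_standard: 80
  goal_sbp_frail: 135
  goal_dbp_frail: 85
  # office-BP inclusion screen
  incl_office_sbp: 135
  incl_office_dbp: 85
  incl_recent_months: 6
  incl_lookback_months: 18
  incl_n_readings: 3
  # orthostatic hypotension postural test (drop, mmHg)
  oh_sbp_drop: 20
  oh_dbp_drop: 10
  # critical-value alerting
  alert_low_sbp: 90
  alert_high_dbp: 120
  alert_high_sbp: 200
  alert_sbp_190: 190
  alert_sbp_180: 180
  alert_sbp_190_days: 2
  alert_sbp_180_days: 3
  alert_window_days: 7
  # titration safety floor
  safety_floor_sbp: 105
  safety_floor_dbp: 50
  hr_floor_bb: 55
  # weekly aggregation
  outlier_sd: 3
  optimal_readings: 28
  optimal_days: 7
  minimal_readings: 12
  minimal_days: 3
  # titration cadence (weeks on a dose before the next change)
  titration_lockout_weeks: 1
  titration_lockout_weeks_mra: 6
  maintenance_confirm_weeks: 2
  # thiazide up-titration margin (mmHg from goal)
  chlorthalidone_margin: 10
  # lab gates (mmol/L, ml/min/1.73 m2, mg/dL)
  k_max_raas: 5.2
  k_warn_raas: 4.5
  k_min_td: 3.5
  na_min_td: 135
  na_warn_td: 140
  k_warn_td: 4.2
  egfr_min: 30
  egfr_raas_pathway: 60
  uacr_pathway: 30
  creat_rise_pct: 30
  k_rise_pct: 15
  k_abs_for_rise: 5.0
  egfr_drop_pct: 30
  baseline_lab_max_months: 12
  # lifestyle-first gate (stage-1 band, medication-naive, low ASCVD risk)
  lifestyle_sbp_max: 140
  lifestyle_dbp_max: 90
  ascvd_low_risk: 0.10
  lifestyle_trial_months: 2
  # lab scheduling (weeks after a dose change)
  post_titration_lab_window_weeks: [1, 2]
  final_lab_window_weeks: 4
  # eligibility gates
  weight_limit_female: 270
  weight_limit_male: 290
  age_min: 26
  age_min_dm: 40
  age_max: 80
  abpm_months: 12
  # childbearing-potential age ceiling
  childbearing_age_max: 45

# RAAS slot policy: program-default potent ARB, agents to switch away from
raas_policy:
  default_arb: irbesartan
  potent_arbs: [irbesartan, valsartan]
  avoid_agents: [losartan]
  titrate_in_place: [lisinopril]

# Per-agent dose ladders.  start_step indexes `steps_mg` (1-based); the
# conservative start is one step below start_step, floored at step 1.
dosing_table:
  amlodipine:
    class: CCB
    steps_mg: [2.5, 5, 10]
    start_step: 2
    requires_labs: false
    once_daily: true
  irbesartan:
    class: ARB
    steps_mg: [75, 150, 300]
    start_step: 2
    requires_labs: true
    once_daily: true
  valsartan:
    class: ARB
    steps_mg: [80, 160, 320]
    start_step: 2
    requires_labs: true
    once_daily: true
  losartan:
    class: ARB
    steps_mg: [25, 50, 100]
    start_step: 2
    requires_labs: true
    once_daily: true
  lisinopril:
    class: ACEI
    steps_mg: [10, 20, 40]
    start_step: 1
    requires_labs: true
    once_daily: true
  hctz:
    class: TD
    steps_mg: [12.5, 25]
    start_step: 1
    requires_labs: true
    once_daily: true
  chlorthalidone:
    class: TD
    steps_mg: [25]
    start_step: 1
    requires_labs: true
    once_daily: true
  spironolactone:
    class: MRA
    steps_mg: [12.5, 25, 50]
    start_step: 1
    requires_labs: true
    once_daily: true
  eplerenone:
    class: MRA
    steps_mg: [25, 50]
    start_step: 1
    requires_labs: true
    once_daily: true
  labetalol:
    class: BB
    steps_mg: [200, 400, 600]
    start_step: 1
    requires_labs: false
    once_daily: false
  metoprolol:
    class: BB
    steps_mg: [25, 50, 100, 200]
    start_step: 1
    requires_labs: false
    once_daily: true

# Single-pill combination products offered once doses are stable
combinations:
  - components: [irbesartan, hctz]
    product: irbesartan/HCTZ
  - components: [valsartan, hctz]
    product: valsartan/HCTZ
  - components: [lisinopril, hctz]
    product: lisinopril/HCTZ
combo_stable_weeks: 4
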