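# Shared fixture builders. All fixtures are constructed in code.

# A full week of home readings (4/day x 7 days), constant or vector-valued.
week_stream <- function(sbp, dbp, hr = 72, start = as.Date("2022-01-03")) {
  dates <- rep(seq(start, by = 1, length.out = 7), each = 4)
  hhmm <- rep(c("07:30:00", "07:32:00", "19:30:00", "19:32:00"), 7)
  bp_stream(paste(dates, hhmm), sbp, dbp, hr = hr, context = "home")
}

# Weekly summary + goal classification for a constant week.
week_summary <- function(sbp, dbp, hr = 72, frail = FALSE,
                         cfg = default_config()) {
  s <- weekly_average(week_stream(sbp, dbp, hr), as.Date("2022-01-03"), cfg)
  list(summary = s, goal = goal_status(s, frail, cfg))
}

normal_labs <- function(draw_date = "2021-12-15", k = 4.0, na = 140,
                        creatinine = 1.0, egfr = 80, uacr = 10,
                        role = "baseline") {
  lab_panel(draw_date, k, na, creatinine, egfr, uacr, role = role)
}

std_profile <- function(...) {
  defaults <- list(patient_id = "t-001", age = 55, sex = "male",
                   ascvd_risk_10yr = 0.15, medication_naive = FALSE)
  args <- utils::modifyList(defaults, list(...))
  do.call(patient_profile, args)
}

std_pathway <- function(pathway = "STANDARD", covid_mode = FALSE) {
  structure(list(pathway = pathway, covid_mode = covid_mode),
            class = "htn_pathway")
}

# Regimen builders anchored well before the default decision date so the
# one-week lockout is expired.
med <- function(agent, step, changed = "2021-11-01", intolerant = FALSE) {
  medication_state(agent, step, start_date = "2021-10-01",
                   last_change_date = changed, intolerant = intolerant)
}

max_three_drug <- function() {
  list(med("amlodipine", 3), med("irbesartan", 3), med("chlorthalidone", 1))
}

DECISION_DATE <- as.Date("2022-01-10")
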