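# Domain record constructors.  All records are validated S3 lists (or, for
# BP streams, plain data frames) so downstream rules can assume their
# invariants.

#' Construct a patient profile
#'
#' The demographic, comorbidity and frailty facts that drive eligibility
#' screening and treatment-pathway assignment. Frailty follows the program
#' definition (assistive-device use or confirmed non-mechanical falls within
#' 12 months) and relaxes the BP goal; childbearing potential (female, under
#' the configured age ceiling, no contraception) routes around
#' RAAS blockade entirely.
#'
#' @param patient_id Opaque identifier string.
#' @param age Age in whole years.
#' @param sex `"male"` or `"female"`.
#' @param weight_lb Body weight in pounds (cuff-fit exclusion input).
#' @param frail Program frailty flag.
#' @param contraception Reliable contraception in use (meaningful for
#'   female sex only).
#' @param diabetes Type 1 or 2 diabetes mellitus.
#' @param heart_failure_reduced_EF,severe_aortic_stenosis,bilateral_renal_artery_stenosis,pregnant_or_breastfeeding,orthostatic_hypotension,terminal_condition
#'   Exclusion-criterion flags.
#' @param can_consent Able to consent to the program.
#' @param ascvd_risk_10yr 10-year ASCVD risk as a fraction in `[0, 1]`, or
#'   `NA` when unknown.
#' @param medication_naive No current or prior antihypertensive therapy.
#' @param current_meds List of [medication_state()] records.
#' @param reactive_airway Reactive airway disease (steers beta-blocker
#'   selection toward a cardioselective agent).
#' @return A list of class `htn_profile`.
#' @export
patient_profile <- function(patient_id,
                            age,
                            sex = c("male", "female"),
                            weight_lb = 180,
                            frail = FALSE,
                            contraception = FALSE,
                            diabetes = FALSE,
                            heart_failure_reduced_EF = FALSE,
                            severe_aortic_stenosis = FALSE,
                            bilateral_renal_artery_stenosis = FALSE,
                            pregnant_or_breastfeeding = FALSE,
                            orthostatic_hypotension = FALSE,
                            terminal_condition = FALSE,
                            can_consent = TRUE,
                            ascvd_risk_10yr = NA_real_,
                            medication_naive = TRUE,
                            current_meds = list(),
                            reactive_airway = FALSE) {
  sex <- match.arg(sex)
  stopifnot(is.numeric(age), age >= 0, is.numeric(weight_lb), weight_lb > 0)
  if (!is.na(ascvd_risk_10yr)) {
    stopifnot(ascvd_risk_10yr >= 0, ascvd_risk_10yr <= 1)
  }
  structure(list(
    patient_id = as.character(patient_id),
    age = as.integer(age), sex = sex, weight_lb = weight_lb,
    frail = isTRUE(frail), contraception = isTRUE(contraception),
    diabetes = isTRUE(diabetes),
    heart_failure_reduced_EF = isTRUE(heart_failure_reduced_EF),
    severe_aortic_stenosis = isTRUE(severe_aortic_stenosis),
    bilateral_renal_artery_stenosis = isTRUE(bilateral_renal_artery_stenosis),
    pregnant_or_breastfeeding = isTRUE(pregnant_or_breastfeeding),
    orthostatic_hypotension = isTRUE(orthostatic_hypotension),
    terminal_condition = isTRUE(terminal_condition),
    can_consent = isTRUE(can_consent),
    ascvd_risk_10yr = ascvd_risk_10yr,
    medication_naive = isTRUE(medication_naive),
    current_meds = current_meds,
    reactive_airway = isTRUE(reactive_airway)
  ), class = "htn_profile")
}

#' Construct a single BP reading
#'
#' @param timestamp Date-time of measurement (coerced to POSIXct, UTC).
#' @param sbp,dbp Systolic and diastolic pressure, mmHg; `sbp > dbp > 0`.
#' @param hr Heart rate, bpm (optional).
#' @param context One of `"home"`, `"office"`, `"standing"`, `"seated"`.
#' @return One-row data frame with columns
#'   `timestamp, sbp, dbp, hr, context`.
#' @export
bp_reading <- function(timestamp, sbp, dbp, hr = NA_real_,
                       context = c("home", "office", "standing", "seated")) {
  context <- match.arg(context)
  ts <- as.POSIXct(timestamp, tz = "UTC")
  if (is.na(ts)) stop("unparseable timestamp")
  if (!(sbp > dbp && dbp > 0)) stop("invalid reading: require sbp > dbp > 0")
  data.frame(timestamp = ts, sbp = as.numeric(sbp), dbp = as.numeric(dbp),
             hr = as.numeric(hr), context = context,
             stringsAsFactors = FALSE)
}

#' Construct a BP reading stream
#'
#' Vectorised convenience wrapper over [bp_reading()]; validates every row.
#'
#' @param timestamp,sbp,dbp,hr,context Vectors, recycled to a common length.
#' @return Data frame of readings, one row per measurement.
#' @export
bp_stream <- function(timestamp, sbp, dbp, hr = NA_real_, context = "home") {
  ts <- as.POSIXct(timestamp, tz = "UTC")
  n <- max(length(ts), length(sbp), length(dbp))
  out <- data.frame(
    timestamp = rep_len(ts, n),
    sbp = as.numeric(rep_len(sbp, n)),
    dbp = as.numeric(rep_len(dbp, n)),
    hr = as.numeric(rep_len(hr, n)),
    context = rep_len(as.character(context), n),
    stringsAsFactors = FALSE
  )
  bad <- which(!(out$sbp > out$dbp & out$dbp > 0) | is.na(out$timestamp))
  if (length(bad)) stop("invalid reading(s) at position(s): ",
                        paste(bad, collapse = ", "))
  out
}

reading_date <- function(readings) {
  as.Date(format(readings$timestamp, tz = "UTC"))
}

#' Construct a lab panel
#'
#' A basic metabolic panel (plus optional urine microalbumin/creatinine
#' ratio) with its draw date and its role relative to the program: the
#' enrollment `baseline` panel anchors all percentage-change rules, a
#' `followup` panel is the "most recent" panel the gates test.
#'
#' @param draw_date Draw date (coerced to `Date`).
#' @param k Serum potassium, mmol/L.
#' @param na Serum sodium, mmol/L.
#' @param creatinine Serum creatinine, mg/dL.
#' @param egfr Estimated GFR, ml/min/1.73 m2.
#' @param uacr Urine microalbumin/creatinine ratio, mg/g Cr (optional).
#' @param role `"baseline"` or `"followup"`.
#' @return A list of class `htn_labs`.
#' @export
lab_panel <- function(draw_date, k, na, creatinine, egfr, uacr = NA_real_,
                      role = c("baseline", "followup")) {
  role <- match.arg(role)
  vals <- c(k = k, na = na, creatinine = creatinine, egfr = egfr)
  if (any(!is.na(vals) & vals <= 0) || (!is.na(uacr) && uacr < 0)) {
    stop("invalid lab panel: analyte values must be positive")
  }
  structure(list(
    draw_date = as.Date(draw_date), k = k, na = na,
    creatinine = creatinine, egfr = egfr, uacr = uacr, role = role
  ), class = "htn_labs")
}

#' Construct a medication state
#'
#' One agent in the current regimen: its position on the configured dose
#' ladder, when it last changed (drives titration lockouts and lab
#' scheduling), and whether the patient tolerates it.
#'
#' @param agent Agent name; must key into the dosing table.
#' @param dose_step 1-based index into the agent's configured dose steps.
#' @param start_date Date therapy with this agent began.
#' @param last_change_date Date of the most recent dose change (defaults to
#'   `start_date`).
#' @param intolerant Documented intolerance (treated as a terminal state for
#'   this agent's ladder).
#' @param cfg Program configuration (used to validate the step and derive
#'   `at_max`).
#' @return A list of class `htn_med` with derived logical field `at_max`.
#' @export
medication_state <- function(agent, dose_step = NULL, start_date = Sys.Date(),
                             last_change_date = start_date,
                             intolerant = FALSE, cfg = default_config()) {
  a <- agent_info(agent, cfg)
  if (is.null(dose_step)) dose_step <- starting_step(agent, cfg = cfg)
  dose_step <- as.integer(dose_step)
  if (dose_step < 1 || dose_step > length(a$steps_mg)) {
    stop("dose_step ", dose_step, " out of range for ", agent)
  }
  structure(list(
    agent = agent, drug_class = a$class, dose_step = dose_step,
    dose_mg = as.numeric(a$steps_mg[[dose_step]]),
    start_date = as.Date(start_date),
    last_change_date = as.Date(last_change_date),
    intolerant = isTRUE(intolerant),
    at_max = dose_step == length(a$steps_mg)
  ), class = "htn_med")
}

#' @export
print.htn_med <- function(x, ...) {
  cat(sprintf("<%s %g mg (step %d%s, %s)%s>\n", x$agent, x$dose_mg,
              x$dose_step, if (x$at_max) ", max" else "", x$drug_class,
              if (x$intolerant) " INTOLERANT" else ""))
  invisible(x)
}

# Internal: one engine decision.
recommendation <- function(action, agent = NULL, target_dose_step = NULL,
                           rationale_codes = character(),
                           requires_lab_gate = FALSE) {
  carries <- action %in% c("START", "TITRATE", "SWITCH", "ADD")
  if (carries && (is.null(agent) || is.null(target_dose_step))) {
    stop("internal error: ", action, " must carry agent and target_dose_step")
  }
  if (!carries) {
    agent <- NULL
    target_dose_step <- NULL
  }
  structure(list(
    action = action, agent = agent,
    target_dose_step = if (!is.null(target_dose_step)) as.integer(target_dose_step),
    rationale_codes = as.character(rationale_codes),
    requires_lab_gate = isTRUE(requires_lab_gate)
  ), class = "htn_recommendation")
}

#' @export
print.htn_recommendation <- function(x, ...) {
  cat("<recommendation>", x$action)
  if (!is.null(x$agent)) cat(" ", x$agent, " -> step ", x$target_dose_step, sep = "")
  if (x$requires_lab_gate) cat(" [lab gate]")
  cat("\n  rationale:", paste(x$rationale_codes, collapse = ", "), "\n")
  invisible(x)
}

# -- regimen helpers ---------------------------------------------------------

validate_regimen <- function(regimen, cfg = default_config()) {
  if (!length(regimen)) return(invisible(TRUE))
  classes <- vapply(regimen, function(m) m$drug_class, character(1))
  if (sum(classes %in% c("ARB", "ACEI")) > 1) {
    stop("validation error: regimen carries two RAAS blockers (ARB/ACEI share one slot)")
  }
  agents <- vapply(regimen, function(m) m$agent, character(1))
  if (anyDuplicated(agents)) stop("validation error: duplicate agent in regimen")
  invisible(TRUE)
}

meds_of_class <- function(regimen, drug_class) {
  want <- if (identical(drug_class, "RAAS")) c("ARB", "ACEI") else drug_class
  Filter(function(m) m$drug_class %in% want, regimen)
}

last_changed_med <- function(regimen) {
  if (!length(regimen)) return(NULL)
  dates <- vapply(regimen, function(m) as.numeric(m$last_change_date), numeric(1))
  regimen[[which.max(dates)]]
}
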