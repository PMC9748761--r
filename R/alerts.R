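# Daily critical-value scanning and alarm-symptom triage.
#
# The scanner re-evaluates a trailing 7-day window at each daily report.
# Single-day rules (SBP <= 90, DBP >= 120, SBP >= 200) emit one event per
# qualifying calendar date; the multi-day rules count *distinct* dates in
# the window with any qualifying reading (2 days of SBP >= 190; 3 days of
# SBP >= 180).  A day qualifies if any reading that day crosses the
# threshold, so a 200 reading also counts toward the 190 and 180 day
# counts.  Events are deduplicated per (type, window end).

.alarm_symptoms <- c("chest_pain", "acute_shortness_of_breath",
                     "severe_headache", "oropharyngeal_swelling",
                     "unclear_thinking", "visual_changes", "nausea_vomiting")

alert_event <- function(alert_type, trigger_dates, window) {
  structure(list(
    alert_type = alert_type,
    trigger_dates = sort(unique(as.Date(trigger_dates))),
    window = as.Date(window)
  ), class = "htn_alert")
}

#' @export
print.htn_alert <- function(x, ...) {
  cat(sprintf("<alert %s> %s (window %s..%s)\n", x$alert_type,
              paste(format(x$trigger_dates), collapse = ", "),
              format(x$window[1]), format(x$window[2])))
  invisible(x)
}

#' Scan home readings for critical BP values
#'
#' @param readings Data frame of home readings (see [bp_stream()]).
#' @param as_of Report date; the trailing window is
#'   `[as_of - 6 days, as_of]`.
#' @param cfg Program configuration.
#' @return List of alert events, each with `alert_type`
#'   (`LOW_SBP_90`, `HIGH_DBP_120`, `HIGH_SBP_200`, `SBP_190_X2`,
#'   `SBP_180_X3`), the qualifying `trigger_dates`, and the scan `window`.
#'   Empty input yields an empty list.
#' @examples
#' bp <- bp_stream("2022-01-05 08:00", 205, 100)
#' scan_critical(bp, as_of = as.Date("2022-01-10"))
#' @export
scan_critical <- function(readings, as_of, cfg = default_config()) {
  th <- cfg$thresholds
  as_of <- as.Date(as_of)
  window <- c(as_of - (th$alert_window_days - 1), as_of)
  events <- list()
  if (is.null(readings) || !nrow(readings)) return(events)
  dates <- reading_date(readings)
  in_win <- dates >= window[1] & dates <= window[2]
  readings <- readings[in_win, , drop = FALSE]
  dates <- dates[in_win]
  if (!nrow(readings)) return(events)

  single_day <- function(hit, type) {
    days <- unique(dates[hit])
    lapply(sort(days), function(d) alert_event(type, d, window))
  }
  events <- c(
    events,
    single_day(readings$sbp <= th$alert_low_sbp, "LOW_SBP_90"),
    single_day(readings$dbp >= th$alert_high_dbp, "HIGH_DBP_120"),
    single_day(readings$sbp >= th$alert_high_sbp, "HIGH_SBP_200")
  )
  days_190 <- unique(dates[readings$sbp >= th$alert_sbp_190])
  if (length(days_190) >= th$alert_sbp_190_days) {
    events <- c(events, list(alert_event("SBP_190_X2", days_190, window)))
  }
  days_180 <- unique(dates[readings$sbp >= th$alert_sbp_180])
  if (length(days_180) >= th$alert_sbp_180_days) {
    events <- c(events, list(alert_event("SBP_180_X3", days_180, window)))
  }
  events
}

#' Patient-facing instruction for an alert
#'
#' A high-SBP (>= 200) reading without alarm symptoms, or a low-SBP
#' (<= 90) reading with dizziness/lightheadedness, is handled by the
#' patient rechecking BP in one hour with attention to technique; if the
#' alerting level or symptoms persist after the recheck the patient calls
#' the program (off hours, their PCP). Multi-day window rules and the
#' remaining single-day rules go to clinician triage on the daily report.
#'
#' @param event An alert event from [scan_critical()].
#' @param symptomatic_dizziness Dizziness or lightheadedness reported
#'   (relevant to the low-SBP rule).
#' @param persisted_after_recheck Alerting values or symptoms persisted on
#'   the 1-hour recheck.
#' @return One of `"RECHECK_1H"`, `"CALL_PROGRAM"`, `"CLINICIAN_TRIAGE"`.
#' @export
patient_instruction <- function(event, symptomatic_dizziness = FALSE,
                                persisted_after_recheck = FALSE) {
  type <- event$alert_type
  if (type %in% c("SBP_190_X2", "SBP_180_X3", "HIGH_DBP_120")) {
    return("CLINICIAN_TRIAGE")
  }
  recheck <- (type == "HIGH_SBP_200") ||
    (type == "LOW_SBP_90" && isTRUE(symptomatic_dizziness))
  if (!recheck) return("CLINICIAN_TRIAGE")
  if (isTRUE(persisted_after_recheck)) "CALL_PROGRAM" else "RECHECK_1H"
}

#' Alarm-symptom triage
#'
#' The alarm-symptom list is a closed enumeration (chest pain, acute
#' shortness of breath, severe headache, throat/tongue/lip/mouth swelling,
#' unclear thinking, visual changes, nausea/vomiting). Any reported
#' symptom directs the patient to call EMS with immediate notification of
#' the program clinical leads and pharmacist.
#'
#' @param symptoms Character vector of reported symptoms.
#' @return `"CALL_EMS_AND_NOTIFY"` if any symptom is present, else
#'   `"none"`.
#' @export
triage_symptoms <- function(symptoms) {
  symptoms <- as.character(symptoms)
  unknown <- setdiff(symptoms, .alarm_symptoms)
  if (length(unknown)) {
    stop("input error: unknown alarm symptom(s): ",
         paste(unknown, collapse = ", "))
  }
  if (length(symptoms)) "CALL_EMS_AND_NOTIFY" else "none"
}

#' Alarm-symptom enumeration
#'
#' @return Character vector of the recognised alarm symptoms.
#' @export
alarm_symptoms <- function() .alarm_symptoms
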