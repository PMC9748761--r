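# Home-BP monitoring: measurement schedules, weekly aggregation with
# per-channel outlier exclusion, goal classification, and program-state
# transitions.
#
# Aggregation notes: outliers are excluded per channel (an aberrant SBP
# removes only that SBP from the SBP mean; its paired DBP survives), in a
# single pass, using the week's own sample SD (n - 1 denominator).  Heart
# rate is averaged without exclusion.

#' Generate a home-BP measurement schedule
#'
#' Twice daily (morning and evening, before medications), in duplicate:
#' four readings per day. The optimal window spans 7 consecutive days
#' (28 readings); the minimal window 3 days (12 readings).
#'
#' @param window `"optimal"` or `"minimal"`.
#' @param start First scheduled date.
#' @param cfg Program configuration.
#' @return Data frame with columns `date`, `session` (`"am"`/`"pm"`) and
#'   `replicate` (1 or 2), one row per scheduled measurement slot.
#' @export
generate_schedule <- function(window = c("optimal", "minimal"), start,
                              cfg = default_config()) {
  window <- match.arg(window)
  th <- cfg$thresholds
  n_days <- if (window == "optimal") th$optimal_days else th$minimal_days
  start <- as.Date(start)
  out <- expand.grid(
    replicate = 1:2, session = c("am", "pm"),
    date = start + seq_len(n_days) - 1L,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out[, c("date", "session", "replicate")]
}

channel_stats <- function(x, outlier_sd) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(list(mean = NA_real_, n_excluded = 0L))
  }
  m <- mean(x)
  s <- stats::sd(x) # sample SD; NA for n = 1
  if (is.na(s) || s == 0) {
    return(list(mean = m, n_excluded = 0L))
  }
  keep <- abs(x - m) <= outlier_sd * s
  list(mean = mean(x[keep]), n_excluded = sum(!keep))
}

#' Weekly home-BP average with outlier exclusion
#'
#' For each channel (SBP and DBP independently) the mean and sample SD are
#' computed over all readings in the window; values more than
#' `outlier_sd` (default 3) SDs from the mean are excluded and the channel
#' mean is recomputed over the survivors. Sufficiency is graded from the
#' reading count and number of distinct calendar days:
#' optimal = 28 readings over 7 days, minimal = 12 over 3; anything less is
#' insufficient and carries no usable means for goal classification.
#'
#' @param readings Data frame of home readings (see [bp_stream()]); all
#'   rows must fall within `[window_start, window_start + 7 days)`.
#' @param window_start First date of the aggregation window.
#' @param cfg Program configuration.
#' @return A list of class `htn_weekly_summary`: window start, counts,
#'   per-channel exclusion counts, post-exclusion means, mean HR,
#'   `distinct_days` and a `sufficiency` grade.
#' @export
weekly_average <- function(readings, window_start, cfg = default_config()) {
  th <- cfg$thresholds
  window_start <- as.Date(window_start)
  if (!is.null(readings) && nrow(readings)) {
    dates <- reading_date(readings)
    if (any(dates < window_start | dates >= window_start + 7)) {
      stop("readings fall outside the 7-day window starting ", window_start)
    }
  } else {
    dates <- as.Date(character())
  }
  n <- if (is.null(readings)) 0L else nrow(readings)
  sbp <- channel_stats(readings$sbp, th$outlier_sd)
  dbp <- channel_stats(readings$dbp, th$outlier_sd)
  hr <- if (n && any(!is.na(readings$hr))) mean(readings$hr, na.rm = TRUE) else NA_real_
  distinct_days <- length(unique(dates))
  sufficiency <- if (n >= th$optimal_readings && distinct_days >= th$optimal_days) {
    "optimal"
  } else if (n >= th$minimal_readings && distinct_days >= th$minimal_days) {
    "minimal"
  } else {
    "insufficient"
  }
  structure(list(
    window_start = window_start,
    n_readings = n,
    n_excluded_sbp = sbp$n_excluded,
    n_excluded_dbp = dbp$n_excluded,
    mean_sbp = sbp$mean,
    mean_dbp = dbp$mean,
    mean_hr = hr,
    distinct_days = distinct_days,
    sufficiency = sufficiency
  ), class = "htn_weekly_summary")
}

#' @export
print.htn_weekly_summary <- function(x, ...) {
  cat(sprintf("<weekly BP> %s: %d readings/%d days [%s] mean %.1f/%.1f (excl %d/%d)\n",
              format(x$window_start), x$n_readings, x$distinct_days,
              x$sufficiency, x$mean_sbp, x$mean_dbp,
              x$n_excluded_sbp, x$n_excluded_dbp))
  invisible(x)
}

#' Classify a weekly summary against the BP goal
#'
#' Above goal iff the weekly mean SBP or DBP is at or above its goal
#' (130/80 mmHg standard; 135/85 with frailty). `near_goal_within_margin`
#' is true when above goal but every channel that is above goal sits less
#' than the chlorthalidone margin (10 mmHg) from it — the condition for the
#' thiazide up-titration switch. `safety_floor_flag` marks weekly means
#' below the titration safety floor (SBP < 105 or DBP < 50); the
#' heart-rate clause of the safety conversation is evaluated by the
#' titration engine, which knows beta-blocker status.
#'
#' @param summary An [weekly_average()] result with sufficiency better than
#'   `"insufficient"`.
#' @param frail Program frailty flag.
#' @param cfg Program configuration.
#' @return A list of class `htn_goal_status`: `status`
#'   (`"at_goal"`/`"above_goal"`), `near_goal_within_margin`,
#'   `safety_floor_flag`, and the goals applied.
#' @export
goal_status <- function(summary, frail = FALSE, cfg = default_config()) {
  th <- cfg$thresholds
  if (identical(summary$sufficiency, "insufficient")) {
    stop("data-sufficiency error: cannot classify an insufficient week")
  }
  goal_sbp <- if (frail) th$goal_sbp_frail else th$goal_sbp_standard
  goal_dbp <- if (frail) th$goal_dbp_frail else th$goal_dbp_standard
  above_sbp <- summary$mean_sbp >= goal_sbp
  above_dbp <- summary$mean_dbp >= goal_dbp
  above <- above_sbp || above_dbp
  near <- FALSE
  if (above) {
    margins <- c(
      if (above_sbp) summary$mean_sbp - goal_sbp,
      if (above_dbp) summary$mean_dbp - goal_dbp
    )
    near <- all(margins < th$chlorthalidone_margin)
  }
  structure(list(
    status = if (above) "above_goal" else "at_goal",
    near_goal_within_margin = near,
    safety_floor_flag = summary$mean_sbp < th$safety_floor_sbp ||
      summary$mean_dbp < th$safety_floor_dbp,
    goal_sbp = goal_sbp, goal_dbp = goal_dbp
  ), class = "htn_goal_status")
}

.program_states <- c("enrolled_baseline", "active_titration", "maintenance",
                     "white_coat", "referred", "withdrawn")

#' Program-state transition after a weekly report
#'
#' At-goal before any medication change diagnoses white-coat
#' hypertension/effect (maintenance handling); at-goal at least 2 weeks
#' after a titration confirms control and enters maintenance (pending
#' labs); an above-goal week puts or keeps the patient in active
#' titration. Undefined transitions are no-ops with a warning, and an
#' insufficient week never moves the state.
#'
#' @param state Current program state.
#' @param summary Weekly summary for the closing window.
#' @param frail Program frailty flag.
#' @param any_med_change_yet Has any program medication change occurred?
#' @param weeks_since_titration Whole or fractional weeks since the last
#'   medication change (`Inf` if none).
#' @param cfg Program configuration.
#' @return The next program state (character scalar).
#' @export
classify_transition <- function(state, summary, frail = FALSE,
                                any_med_change_yet = FALSE,
                                weeks_since_titration = Inf,
                                cfg = default_config()) {
  stopifnot(state %in% .program_states)
  if (identical(summary$sufficiency, "insufficient")) return(state)
  if (state %in% c("referred", "withdrawn")) return(state)
  goal <- goal_status(summary, frail, cfg)
  at_goal <- goal$status == "at_goal"
  th <- cfg$thresholds
  if (state == "enrolled_baseline") {
    if (at_goal && !any_med_change_yet) return("white_coat")
    if (!at_goal) return("active_titration")
    return(state)
  }
  if (state == "active_titration") {
    if (at_goal && weeks_since_titration >= th$maintenance_confirm_weeks) {
      return("maintenance")
    }
    return(state)
  }
  if (state %in% c("maintenance", "white_coat")) {
    if (!at_goal) return("active_titration")
    return(state)
  }
  warning("undefined transition from ", state, "; state unchanged")
  state
}
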