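# Program inclusion/exclusion screening.
#
# Inclusion is satisfied by office BP alone: either the single most recent
# office reading within 6 months crosses 135/85, or the mean of the three
# most recent readings within 18 months does (either channel).  Exclusions
# are screened as independent coded rules; a candidate is eligible iff an
# inclusion rule fired and no exclusion code did.  The office-BP file is
# assumed pre-filtered to regular clinic visits.

months_before <- function(as_of, months) {
  seq(from = as_of, by = paste0("-", months, " months"), length.out = 2)[2]
}

#' Office-BP inclusion screen
#'
#' @param office_bps Data frame of office readings (`timestamp`, `sbp`,
#'   `dbp`); order is immaterial. An empty history yields `"none"`.
#' @param as_of Screening date.
#' @param cfg Program configuration.
#' @return `"recent_office_bp"`, `"mean_of_three"`, or `"none"`.
#' @examples
#' bp <- bp_stream("2021-11-01 09:00", 142, 82, context = "office")
#' assess_inclusion(bp, as_of = as.Date("2022-01-01"))
#' @export
assess_inclusion <- function(office_bps, as_of, cfg = default_config()) {
  th <- cfg$thresholds
  as_of <- as.Date(as_of)
  if (is.null(office_bps) || !nrow(office_bps)) return("none")
  dates <- reading_date(office_bps)
  keep <- dates <= as_of
  office_bps <- office_bps[keep, , drop = FALSE]
  dates <- dates[keep]
  if (!nrow(office_bps)) return("none")
  ord <- order(dates, decreasing = TRUE)
  if (anyDuplicated(dates)) {
    warning("tied office-visit dates; ties broken by record order")
  }
  office_bps <- office_bps[ord, , drop = FALSE]
  dates <- dates[ord]

  # rule 1: single most recent reading, within 6 months
  if (dates[1] >= months_before(as_of, th$incl_recent_months) &&
      (office_bps$sbp[1] >= th$incl_office_sbp ||
       office_bps$dbp[1] >= th$incl_office_dbp)) {
    return("recent_office_bp")
  }
  # rule 2: mean of the three most recent readings within 18 months
  in_window <- dates >= months_before(as_of, th$incl_lookback_months)
  recent <- office_bps[in_window, , drop = FALSE]
  if (nrow(recent) >= th$incl_n_readings) {
    top <- recent[seq_len(th$incl_n_readings), , drop = FALSE]
    if (mean(top$sbp) >= th$incl_office_sbp ||
        mean(top$dbp) >= th$incl_office_dbp) {
      return("mean_of_three")
    }
  }
  "none"
}

#' Exclusion-criterion screen
#'
#' Returns every applicable machine-readable exclusion code. The age gate
#' uses the diabetes-specific floor; the weight gate uses sex-specific cuff
#' limits; the ABPM gate fires when a 24-h monitor within the past year
#' showed control. Missing optional inputs (labs) simply suppress the
#' corresponding rule.
#'
#' @param profile An [patient_profile()].
#' @param labs Baseline [lab_panel()], or `NULL` if unavailable.
#' @param abpm_controlled_within_year 24-h ambulatory monitor in the past
#'   year demonstrated SBP < 130 and DBP < 80.
#' @param cfg Program configuration.
#' @return Character vector of exclusion codes (empty when none apply).
#' @export
assess_exclusions <- function(profile, labs = NULL,
                              abpm_controlled_within_year = FALSE,
                              cfg = default_config()) {
  th <- cfg$thresholds
  codes <- character()
  age_floor <- if (profile$diabetes) th$age_min_dm else th$age_min
  if (profile$age < age_floor || profile$age > th$age_max) codes <- c(codes, "AGE_RANGE")
  if (profile$pregnant_or_breastfeeding) codes <- c(codes, "PREGNANT")
  if (profile$heart_failure_reduced_EF) codes <- c(codes, "HFrEF")
  if (profile$severe_aortic_stenosis) codes <- c(codes, "AORTIC_STENOSIS")
  if (profile$bilateral_renal_artery_stenosis) codes <- c(codes, "RAS_BILATERAL")
  if (!is.null(labs) && !is.na(labs$egfr) && labs$egfr < th$egfr_min) {
    codes <- c(codes, "EGFR_LT_30")
  }
  if (profile$orthostatic_hypotension) codes <- c(codes, "OH")
  if (profile$terminal_condition) codes <- c(codes, "TERMINAL")
  if (!profile$can_consent) codes <- c(codes, "CONSENT")
  limit <- if (profile$sex == "female") th$weight_limit_female else th$weight_limit_male
  if (profile$weight_lb > limit) codes <- c(codes, "WEIGHT_CUFF")
  if (isTRUE(abpm_controlled_within_year)) codes <- c(codes, "CONTROLLED_ABPM")
  codes
}

#' Postural orthostatic-hypotension test
#'
#' Flags orthostatic hypotension when BP on standing from a seated position
#' drops by at least the configured systolic (20 mmHg) or diastolic
#' (10 mmHg) amount; the thresholds are inclusive, consistent with standard
#' OH definitions.
#'
#' @param seated,standing Single readings with matching `context`.
#' @param cfg Program configuration.
#' @return `TRUE` if the postural drop meets either threshold.
#' @export
postural_oh_test <- function(seated, standing, cfg = default_config()) {
  th <- cfg$thresholds
  if (!identical(seated$context, "seated") || !identical(standing$context, "standing")) {
    stop("input error: expected contexts seated then standing")
  }
  (seated$sbp - standing$sbp) >= th$oh_sbp_drop ||
    (seated$dbp - standing$dbp) >= th$oh_dbp_drop
}

#' Full eligibility screen
#'
#' @inheritParams assess_exclusions
#' @param office_bps Office-BP history (see [assess_inclusion()]).
#' @param as_of Screening date.
#' @return A list of class `htn_eligibility`: `eligible`,
#'   `inclusion_rule_fired`, `exclusion_codes`.
#' @export
screen_eligibility <- function(profile, office_bps, as_of, labs = NULL,
                               abpm_controlled_within_year = FALSE,
                               cfg = default_config()) {
  rule <- assess_inclusion(office_bps, as_of, cfg)
  codes <- assess_exclusions(profile, labs, abpm_controlled_within_year, cfg)
  structure(list(
    eligible = rule != "none" && length(codes) == 0,
    inclusion_rule_fired = rule,
    exclusion_codes = codes
  ), class = "htn_eligibility")
}

#' @export
print.htn_eligibility <- function(x, ...) {
  cat("<eligibility>", if (x$eligible) "ELIGIBLE" else "INELIGIBLE",
      "| inclusion:", x$inclusion_rule_fired)
  if (length(x$exclusion_codes)) {
    cat(" | exclusions:", paste(x$exclusion_codes, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}
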