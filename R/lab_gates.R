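# Laboratory gating of prescribing by drug class.
#
# CCB and BB need general enrollment labs only and pass vacuously.  The
# lab-requiring classes (ARB/ACEI, TD, MRA) are gated on the most recent
# panel, with percentage-change rules anchored to the enrollment baseline.
# Comparisons use the printed strict/inclusive forms verbatim: e.g. "most
# recent K < 5.2" blocks at exactly 5.2.

gate_result <- function(decision, codes = character()) {
  structure(list(decision = decision, codes = as.character(codes)),
            class = "htn_gate")
}

#' @export
print.htn_gate <- function(x, ...) {
  cat("<lab gate>", x$decision,
      if (length(x$codes)) paste0("[", paste(x$codes, collapse = ", "), "]"), "\n")
  invisible(x)
}

pct_rise <- function(latest, baseline) 100 * (latest - baseline) / baseline

baseline_stale <- function(baseline, as_of, cfg) {
  !is.null(as_of) &&
    baseline$draw_date < months_before(as.Date(as_of),
                                       cfg$thresholds$baseline_lab_max_months)
}

#' Drug-class laboratory gate
#'
#' Decides whether the most recent labs permit starting or titrating an
#' agent of the given class:
#'
#' * ARB/ACEI — blocked by K at or above 5.2 mmol/L, eGFR below
#'   30 ml/min/1.73 m2, or an eGFR drop of 30% or more from baseline.
#' * TD — blocked by K below 3.5, Na below 135, or eGFR below 30.
#' * MRA — blocked as ARB/ACEI plus Na below 135; K strictly between 4.5
#'   and 5.2 passes at the conservative starting dose with a
#'   clinical-lead discussion code.
#' * CCB/BB — pass with no class-specific labs.
#'
#' Advisory (non-blocking) codes accompany a pass: RAAS with eGFR < 60 or
#' K > 4.5; TD with Na < 140 or K < 4.2.
#'
#' @param drug_class One of `"CCB"`, `"ARB"`, `"ACEI"`, `"TD"`, `"MRA"`,
#'   `"BB"`.
#' @param latest Most recent [lab_panel()]; `NULL` blocks lab-requiring
#'   classes.
#' @param baseline Enrollment baseline panel (anchors percentage-change
#'   rules); `NULL` suppresses them.
#' @param as_of Date against which baseline staleness (12 months) is
#'   judged; `NULL` skips the staleness check.
#' @param cfg Program configuration.
#' @return A list of class `htn_gate`: `decision` (`"PASS"`,
#'   `"PASS_CONSERVATIVE"`, `"BLOCK"`, with advisory codes possible on any
#'   pass) and `codes`.
#' @examples
#' base <- lab_panel("2022-01-01", k = 4.0, na = 140, creatinine = 1.0, egfr = 80)
#' check_gate("ARB", lab_panel("2022-03-01", 5.3, 140, 1.0, 78, role = "followup"), base)
#' @export
check_gate <- function(drug_class, latest, baseline = NULL, as_of = NULL,
                       cfg = default_config()) {
  stopifnot(drug_class %in% .drug_classes)
  th <- cfg$thresholds
  if (!class_requires_labs(drug_class)) return(gate_result("PASS"))
  if (is.null(latest)) return(gate_result("BLOCK", "NO_RECENT_LABS"))

  block <- character()
  warn <- character()
  raas_like <- drug_class %in% c("ARB", "ACEI", "MRA")

  if (raas_like && latest$k >= th$k_max_raas) block <- c(block, "K_GE_5_2")
  if (drug_class == "TD" && latest$k < th$k_min_td) block <- c(block, "K_LT_3_5")
  if (drug_class %in% c("TD", "MRA") && latest$na < th$na_min_td) {
    block <- c(block, "NA_LT_135")
  }
  if (latest$egfr < th$egfr_min) block <- c(block, "EGFR_LT_30")
  if (raas_like && !is.null(baseline) &&
      100 * (baseline$egfr - latest$egfr) / baseline$egfr >= th$egfr_drop_pct) {
    block <- c(block, "EGFR_DROP_30PCT")
  }
  if (!is.null(baseline) && baseline_stale(baseline, as_of, cfg)) {
    warn <- c(warn, "STALE_BASELINE")
  }
  if (drug_class %in% c("ARB", "ACEI")) {
    if (latest$egfr < th$egfr_raas_pathway) warn <- c(warn, "EGFR_LT_60")
    if (latest$k > th$k_warn_raas) warn <- c(warn, "K_WARN_GT_4_5")
  }
  if (drug_class == "TD") {
    if (latest$na < th$na_warn_td) warn <- c(warn, "NA_WARN_LT_140")
    if (latest$k < th$k_warn_td) warn <- c(warn, "K_WARN_LT_4_2")
  }
  if (length(block)) return(gate_result("BLOCK", c(block, warn)))
  if (drug_class == "MRA" && latest$k > th$k_warn_raas && latest$k < th$k_max_raas) {
    return(gate_result("PASS_CONSERVATIVE",
                       c("K_GT_4_5_CONSERVATIVE", "DISCUSS_CLINICAL_LEAD", warn)))
  }
  gate_result("PASS", warn)
}

#' Repeat-labs / down-titration trigger after a dose change
#'
#' Follow-up labs against baseline trigger a repeat draw when creatinine
#' rose 30% or more from baseline; for RAAS/MRA additionally when K rose
#' 15% or more from baseline *and* K exceeds 5.0 mmol/L (both conjuncts
#' required); for TD/MRA when Na fell below 135; for TD when K fell below
#' 3.5. A confirmed repeat escalates to down-titration of the associated
#' regimen step (the two-step reading of the protocol's
#' "repeat ... or down-titrate" alternative).
#'
#' @param drug_class Drug class of the most recently changed agent.
#' @param latest,baseline Follow-up and enrollment baseline panels.
#' @param repeat_confirmed Has a repeat draw already confirmed the trigger?
#' @param cfg Program configuration.
#' @return `"NONE"`, `"REPEAT_LABS"`, or `"DOWN_TITRATE"`.
#' @export
repeat_or_downtitrate <- function(drug_class, latest, baseline,
                                  repeat_confirmed = FALSE,
                                  cfg = default_config()) {
  stopifnot(drug_class %in% .drug_classes)
  th <- cfg$thresholds
  if (!class_requires_labs(drug_class)) return("NONE")
  stopifnot(!is.null(latest), !is.null(baseline))
  trigger <- pct_rise(latest$creatinine, baseline$creatinine) >= th$creat_rise_pct
  if (drug_class %in% c("ARB", "ACEI", "MRA")) {
    trigger <- trigger ||
      (pct_rise(latest$k, baseline$k) >= th$k_rise_pct &&
         latest$k > th$k_abs_for_rise)
  }
  if (drug_class %in% c("TD", "MRA")) {
    trigger <- trigger || latest$na < th$na_min_td
  }
  if (drug_class == "TD") {
    trigger <- trigger || latest$k < th$k_min_td
  }
  if (!trigger) return("NONE")
  if (isTRUE(repeat_confirmed)) "DOWN_TITRATE" else "REPEAT_LABS"
}

#' Post-change laboratory schedule for an agent
#'
#' Lab-requiring agents need a basic metabolic panel 1-2 weeks after
#' initiation and after the last titration. When an agent has three or
#' more potential titration steps and previous values were within normal
#' limits, intermediate draws may run every other titration (the skipped
#' draw is reported with `skip = TRUE`). The final-dose draw is never
#' skipped and may fall within 4 weeks of the last change.
#'
#' @param agent Agent name.
#' @param n_changes How many dose changes this agent has had, counting the
#'   initiation as 1.
#' @param at_final_dose Is the agent now at its final configured step?
#' @param previous_labs_wnl Were the previous post-change labs within
#'   normal limits?
#' @param change_date Date of the change being scheduled for.
#' @param cfg Program configuration.
#' @return `NULL` for lab-free agents; otherwise a list of class
#'   `htn_lab_schedule`: `next_draw_window` (earliest, latest),
#'   `reason` (`post_initiation`, `post_titration`,
#'   `every_other_titration`, `final_dose`) and `skip`.
#' @export
schedule_labs <- function(agent, n_changes = 1, at_final_dose = FALSE,
                          previous_labs_wnl = TRUE, change_date = Sys.Date(),
                          cfg = default_config()) {
  a <- agent_info(agent, cfg)
  if (!isTRUE(a$requires_labs)) return(NULL)
  th <- cfg$thresholds
  change_date <- as.Date(change_date)
  win <- th$post_titration_lab_window_weeks
  if (isTRUE(at_final_dose)) {
    sched <- list(
      next_draw_window = c(change_date, change_date + 7 * th$final_lab_window_weeks),
      reason = "final_dose", skip = FALSE
    )
  } else if (n_changes <= 1) {
    sched <- list(
      next_draw_window = change_date + 7 * win,
      reason = "post_initiation", skip = FALSE
    )
  } else {
    # every-other-titration cadence applies mid-ladder with >= 3 steps and
    # reassuring previous values: the even-numbered changes draw, the odd skip
    eligible_skip <- length(a$steps_mg) >= 3 && isTRUE(previous_labs_wnl) &&
      n_changes %% 2 == 0
    sched <- list(
      next_draw_window = change_date + 7 * win,
      reason = if (eligible_skip) "every_other_titration" else "post_titration",
      skip = eligible_skip
    )
  }
  structure(sched, class = "htn_lab_schedule")
}

#' Program-level pharmacist warnings for a pending recommendation
#'
#' Advisory flags generated alongside (never instead of) the hard gates:
#' a pending RAAS recommendation with eGFR < 60 or K > 4.5; a pending TD
#' with Na < 140 or K < 4.2; a pending RAAS or TD with a K rise of more
#' than 15% from baseline together with K > 5 mmol/L (this warning's rise
#' comparison is strict, as printed, unlike the repeat-labs rule's
#' inclusive form).
#'
#' @param pending_class Drug class of the pending recommendation.
#' @param latest,baseline Most recent and enrollment baseline panels.
#' @param cfg Program configuration.
#' @return Character vector of warning codes (possibly empty).
#' @export
program_warnings <- function(pending_class, latest, baseline = NULL,
                             cfg = default_config()) {
  stopifnot(pending_class %in% .drug_classes)
  th <- cfg$thresholds
  codes <- character()
  if (is.null(latest)) return(codes)
  raas <- pending_class %in% c("ARB", "ACEI")
  if (raas && latest$egfr < th$egfr_raas_pathway) codes <- c(codes, "RAAS_EGFR_LT_60")
  if (raas && latest$k > th$k_warn_raas) codes <- c(codes, "RAAS_K_GT_4_5")
  if (pending_class == "TD" && latest$na < th$na_warn_td) codes <- c(codes, "TD_NA_LT_140")
  if (pending_class == "TD" && latest$k < th$k_warn_td) codes <- c(codes, "TD_K_LT_4_2")
  if ((raas || pending_class == "TD") && !is.null(baseline) &&
      pct_rise(latest$k, baseline$k) > th$k_rise_pct &&
      latest$k > th$k_abs_for_rise) {
    codes <- c(codes, "K_RISE_GT_15PCT_AND_GT_5")
  }
  codes
}
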