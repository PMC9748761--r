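# Pathway assignment and the medication-titration state machine.
#
# Drug sequencing by pathway:
#   STANDARD      CCB -> ARB/ACEI -> TD -> (secondary screen, then MRA/BB)
#   RAAS_FIRST    ARB/ACEI -> CCB -> TD -> (as above)
#   CHILDBEARING  CCB -> labetalol (no RAAS, no fourth line; then referral)
#
# The childbearing-potential rule outranks RAAS-first: the RAAS pathway is
# defined over patients *not* of childbearing potential, so a young diabetic
# woman without contraception still goes CCB -> labetalol.
#
# Each engine invocation returns exactly one next step, decided in a fixed
# priority order: at-goal hold, safety conversation, titration lockout,
# lifestyle-first trial, then maximize-before-add walking the pathway
# sequence, the thiazide -> chlorthalidone margin switch, and finally the
# secondary-cause screen / fourth line / specialist referral.

#' Assign a treatment pathway
#'
#' Childbearing potential (female, under the configured age ceiling,
#' without contraception) takes precedence; otherwise diabetes, eGFR below
#' 60 ml/min/1.73 m2, or urine microalbumin/Cr at or above 30 mg/g routes
#' to RAAS blockade first; everyone else starts on the standard (CCB-first)
#' pathway. A missing UACR is treated as below threshold with a warning.
#'
#' @param profile An [patient_profile()].
#' @param labs Baseline [lab_panel()].
#' @param covid_mode Pandemic risk-mitigation flag, carried on the pathway.
#' @param cfg Program configuration.
#' @return A list of class `htn_pathway`: `pathway` (`"STANDARD"`,
#'   `"RAAS_FIRST"`, `"CHILDBEARING"`) and `covid_mode`.
#' @export
assign_pathway <- function(profile, labs, covid_mode = FALSE,
                           cfg = default_config()) {
  th <- cfg$thresholds
  childbearing <- profile$sex == "female" &&
    profile$age < th$childbearing_age_max && !profile$contraception
  uacr <- labs$uacr
  if (is.na(uacr)) {
    warning("UACR unavailable; treated as < ", th$uacr_pathway, " mg/g Cr")
    uacr <- 0
  }
  pathway <- if (childbearing) {
    "CHILDBEARING"
  } else if (profile$diabetes || labs$egfr < th$egfr_raas_pathway ||
             uacr >= th$uacr_pathway) {
    "RAAS_FIRST"
  } else {
    "STANDARD"
  }
  structure(list(pathway = pathway, covid_mode = isTRUE(covid_mode)),
            class = "htn_pathway")
}

#' Select the RAAS agent and action
#'
#' When the ARB/ACEI slot is the indicated next step: a RAAS-naive patient
#' starts the program-default potent ARB; a patient on losartan or on an
#' ACE inhibitor other than lisinopril is switched to the potent ARB; a
#' patient on lisinopril (or already on a potent ARB) titrates in place.
#'
#' @param regimen List of [medication_state()] records.
#' @param cfg Program configuration (RAAS policy: default/potent ARBs,
#'   agents to switch away from).
#' @return List with `agent`, `action` (`"START"`, `"SWITCH"`,
#'   `"TITRATE"`) and `target_dose_step`; `NULL` if the slot is exhausted
#'   (potent agent at maximum dose or intolerant).
#' @export
select_raas_agent <- function(regimen, cfg = default_config()) {
  pol <- cfg$raas_policy
  raas <- meds_of_class(regimen, "RAAS")
  if (length(raas) > 1) {
    stop("validation error: patient on both ARB and ACEI")
  }
  if (!length(raas)) {
    agent <- pol$default_arb
    return(list(agent = agent, action = "START",
                target_dose_step = starting_step(agent, cfg = cfg)))
  }
  med <- raas[[1]]
  keep_in_place <- med$agent %in% c(pol$potent_arbs, pol$titrate_in_place)
  if (!keep_in_place) {
    if (med$intolerant) return(NULL) # class intolerance: do not re-challenge
    agent <- pol$default_arb
    return(list(agent = agent, action = "SWITCH",
                target_dose_step = starting_step(agent, cfg = cfg)))
  }
  if (med$intolerant || med$at_max) return(NULL)
  list(agent = med$agent, action = "TITRATE",
       target_dose_step = med$dose_step + 1L)
}

class_sequence <- function(pathway) {
  switch(pathway,
    STANDARD = c("CCB", "RAAS", "TD"),
    RAAS_FIRST = c("RAAS", "CCB", "TD"),
    CHILDBEARING = c("CCB", "BB"),
    stop("unknown pathway: ", pathway)
  )
}

default_class_agent <- function(drug_class, profile, cfg) {
  switch(drug_class,
    CCB = "amlodipine",
    TD = "hctz",
    MRA = if (profile$sex == "male") "eplerenone" else "spironolactone",
    BB = if (profile$reactive_airway) "metoprolol" else "labetalol",
    stop("no default agent for class ", drug_class)
  )
}

# Escalate an agent already on board for this class slot (titrate in place,
# RAAS potency switch, or the thiazide chlorthalidone up-titration), or NULL.
escalate_existing <- function(drug_class, regimen, goal, cfg) {
  if (identical(drug_class, "RAAS")) {
    if (!length(meds_of_class(regimen, "RAAS"))) return(NULL)
    return(select_raas_agent(regimen, cfg))
  }
  meds <- meds_of_class(regimen, drug_class)
  if (!length(meds)) return(NULL)
  open <- Filter(function(m) !m$intolerant && !m$at_max, meds)
  if (length(open)) {
    m <- open[[1]]
    return(list(agent = m$agent, action = "TITRATE",
                target_dose_step = m$dose_step + 1L))
  }
  if (drug_class == "TD") {
    # chlorthalidone is the thiazide up-titration, offered only when BP sits
    # within the configured margin of goal on every above-goal channel
    agents <- vapply(meds, function(m) m$agent, character(1))
    hctz_max <- any(vapply(meds, function(m) {
      m$agent == "hctz" && m$at_max && !m$intolerant
    }, logical(1)))
    if (hctz_max && !"chlorthalidone" %in% agents &&
        isTRUE(goal$near_goal_within_margin)) {
      return(list(agent = "chlorthalidone", action = "SWITCH",
                  target_dose_step = starting_step("chlorthalidone", cfg = cfg)))
    }
  }
  NULL
}

# Open a class slot that has no agent on board yet, or NULL.
open_new_class <- function(drug_class, regimen, profile, cfg) {
  if (identical(drug_class, "RAAS")) {
    if (length(meds_of_class(regimen, "RAAS"))) return(NULL)
    return(select_raas_agent(regimen, cfg))
  }
  if (length(meds_of_class(regimen, drug_class))) return(NULL)
  agent <- default_class_agent(drug_class, profile, cfg)
  list(agent = agent, action = if (length(regimen)) "ADD" else "START",
       target_dose_step = starting_step(agent, cfg = cfg))
}

# Next move within one class slot, or NULL if the slot is exhausted.
advance_class <- function(drug_class, regimen, profile, goal, cfg) {
  escalate_existing(drug_class, regimen, goal, cfg) %||%
    open_new_class(drug_class, regimen, profile, cfg)
}

hr_too_low <- function(mean_hr, cfg) {
  !is.na(mean_hr) && mean_hr < cfg$thresholds$hr_floor_bb
}

# MRA dose changes are spaced 6 weeks apart regardless of what else moved;
# returns a HOLD recommendation when the proposed step violates that, or NULL.
mra_spacing_hold <- function(step, regimen, as_of, cfg) {
  if (step$action != "TITRATE" ||
      agent_class(step$agent, cfg) != "MRA") return(NULL)
  mra_med <- Filter(function(m) m$agent == step$agent, regimen)[[1]]
  if (as.numeric(as_of - mra_med$last_change_date) / 7 <
      cfg$thresholds$titration_lockout_weeks_mra) {
    return(recommendation("HOLD", rationale_codes = "TITRATION_LOCKOUT"))
  }
  NULL
}

#' Decide the single next titration step
#'
#' The engine's one-decision-per-invocation policy, in priority order:
#' at-goal hold (maintenance pending labs); safety-floor or low-heart-rate
#' physician conversation; titration lockout (1 week, 6 weeks after an MRA
#' change); lifestyle-first trial for medication-naive stage-1 patients
#' with 10-year ASCVD risk below 10%; maximize-the-current-agent before
#' adding the next class of the pathway sequence; the
#' hydrochlorothiazide-to-chlorthalidone switch within 10 mmHg of goal;
#' and, uncontrolled on a maximal conventional 3-drug regimen, the
#' secondary-cause screen, then MRA (potassium permitting) or beta
#' blocker, then specialist referral.
#'
#' Starts and titrations of ARB/ACEI, TD and MRA agents are flagged
#' `requires_lab_gate`; callers run [check_gate()] before prescribing.
#'
#' @param profile An [patient_profile()].
#' @param pathway An [assign_pathway()] result.
#' @param regimen List of [medication_state()] records (the current
#'   program-managed regimen).
#' @param summary The closing week's [weekly_average()] summary.
#' @param goal Its [goal_status()] classification.
#' @param labs Most recent [lab_panel()] (`NULL` if none).
#' @param baseline_labs Enrollment baseline panel.
#' @param as_of Decision date (drives lockout arithmetic).
#' @param secondary_screen `NULL` until a secondary-cause screen has been
#'   ordered and reviewed; afterwards a list with `reviewed_positive`.
#' @param labs_available Pandemic-mode flag: can the patient reach a lab?
#' @param lifestyle_completed A lifestyle-only trial has already been run
#'   (suppresses the lifestyle-first gate on reassessment).
#' @param cfg Program configuration.
#' @return An `htn_recommendation`.
#' @export
next_action <- function(profile, pathway, regimen, summary, goal,
                        labs = NULL, baseline_labs = NULL, as_of,
                        secondary_screen = NULL, labs_available = TRUE,
                        lifestyle_completed = FALSE,
                        cfg = default_config()) {
  th <- cfg$thresholds
  validate_regimen(regimen, cfg)
  as_of <- as.Date(as_of)

  finish <- function(rec) {
    if (isTRUE(pathway$covid_mode)) {
      apply_covid_mode(rec, labs_available, summary, regimen, profile, cfg)
    } else {
      rec
    }
  }

  # (0) at goal: hold, maintenance pending labs
  if (goal$status == "at_goal") {
    return(recommendation("HOLD", rationale_codes = "AT_GOAL_PENDING_LABS"))
  }
  # (1) safety conversation: weekly means below floor, or on a BB with low HR
  if (isTRUE(goal$safety_floor_flag)) {
    return(recommendation("PHYSICIAN_CONVERSATION", rationale_codes = "SAFETY_FLOOR"))
  }
  on_bb <- length(meds_of_class(regimen, "BB")) > 0
  if (on_bb && hr_too_low(summary$mean_hr, cfg)) {
    return(recommendation("PHYSICIAN_CONVERSATION", rationale_codes = "HR_LT_55_ON_BB"))
  }
  # (2) titration lockout
  last <- last_changed_med(regimen)
  if (!is.null(last)) {
    lock <- if (last$drug_class == "MRA") th$titration_lockout_weeks_mra else th$titration_lockout_weeks
    weeks_since <- as.numeric(as_of - last$last_change_date) / 7
    if (weeks_since < lock) {
      return(recommendation("HOLD", rationale_codes = "TITRATION_LOCKOUT"))
    }
  }
  # (3) lifestyle-first trial: naive, stage-1 band, low ASCVD risk
  if (!isTRUE(lifestyle_completed) &&
      profile$medication_naive && !length(regimen) &&
      !is.na(profile$ascvd_risk_10yr) &&
      profile$ascvd_risk_10yr < th$ascvd_low_risk &&
      summary$mean_sbp < th$lifestyle_sbp_max &&
      summary$mean_dbp < th$lifestyle_dbp_max) {
    return(recommendation("LIFESTYLE_TRIAL", rationale_codes = "NAIVE_STAGE1_LOW_ASCVD"))
  }
  # (4)-(6) walk the pathway sequence: maximize every on-board ladder first,
  # then open the next class slot in pathway order
  hypoNa <- !is.null(labs) && !is.na(labs$na) && labs$na < th$na_min_td
  seq_cls <- class_sequence(pathway$pathway)
  seq_cls <- seq_cls[!(seq_cls == "TD" & hypoNa)] # hyponatremia: no thiazide
  # ladders already on board are maximized before any new class is opened,
  # including agents outside this pathway's sequence (RAAS and MRA are never
  # escalated on the childbearing pathway)
  extra_cls <- setdiff(c("CCB", "RAAS", "TD", "MRA", "BB"), seq_cls)
  if (pathway$pathway == "CHILDBEARING") {
    extra_cls <- setdiff(extra_cls, c("RAAS", "MRA"))
  }
  if (hypoNa) extra_cls <- setdiff(extra_cls, "TD")
  step <- NULL
  for (cls in c(seq_cls, extra_cls)) {
    step <- escalate_existing(cls, regimen, goal, cfg)
    if (!is.null(step)) break
  }
  if (is.null(step)) {
    for (cls in seq_cls) {
      step <- open_new_class(cls, regimen, profile, cfg)
      if (!is.null(step)) break
    }
  }
  if (!is.null(step)) {
    if (step$action == "START" && length(regimen)) step$action <- "ADD"
    if (agent_class(step$agent, cfg) == "BB" && hr_too_low(summary$mean_hr, cfg)) {
      return(recommendation("PHYSICIAN_CONVERSATION", rationale_codes = "HR_LT_55_FOR_BB"))
    }
    hold <- mra_spacing_hold(step, regimen, as_of, cfg)
    if (!is.null(hold)) return(hold)
    code <- switch(step$action,
      START = "FIRST_LINE_START", ADD = "MAXIMIZED_PRIOR_AGENT_ADD_NEXT",
      SWITCH = if (step$agent == "chlorthalidone") "HCTZ_MAX_NEAR_GOAL_SWITCH" else "SWITCH_TO_POTENT_ARB",
      TITRATE = "BELOW_MAX_TITRATE"
    )
    return(finish(recommendation(
      step$action, step$agent, step$target_dose_step,
      rationale_codes = c(code, paste0("PATHWAY_", pathway$pathway)),
      requires_lab_gate = class_requires_labs(agent_class(step$agent, cfg))
    )))
  }
  # conventional options exhausted
  if (pathway$pathway == "CHILDBEARING") {
    return(recommendation("REFER_SPECIALIST", rationale_codes = "CHILDBEARING_OPTIONS_EXHAUSTED"))
  }
  # (7) uncontrolled on maximal conventional 3-drug regimen
  if (is.null(secondary_screen)) {
    return(recommendation("ORDER_SECONDARY_LABS",
                          rationale_codes = "UNCONTROLLED_MAX_3_DRUG"))
  }
  if (isTRUE(secondary_screen$reviewed_positive)) {
    return(recommendation("REFER_SPECIALIST", rationale_codes = "SECONDARY_SCREEN_POSITIVE"))
  }
  # fourth line: MRA if potassium permits, else BB (HR >= 55 required)
  mra_step <- advance_class("MRA", regimen, profile, goal, cfg)
  if (!is.null(mra_step)) {
    hold <- mra_spacing_hold(mra_step, regimen, as_of, cfg)
    if (!is.null(hold)) return(hold)
  }
  if (!is.null(mra_step)) {
    gate <- check_gate("MRA", labs, baseline_labs, as_of, cfg)
    if (gate$decision != "BLOCK") {
      step_target <- if (gate$decision == "PASS_CONSERVATIVE" && mra_step$action == "START") {
        starting_step(mra_step$agent, conservative = TRUE, cfg = cfg)
      } else {
        mra_step$target_dose_step
      }
      return(finish(recommendation(
        mra_step$action, mra_step$agent, step_target,
        rationale_codes = c("FOURTH_LINE_MRA", gate$codes),
        requires_lab_gate = TRUE
      )))
    }
  }
  bb_step <- advance_class("BB", regimen, profile, goal, cfg)
  if (!is.null(bb_step)) {
    if (hr_too_low(summary$mean_hr, cfg)) {
      return(recommendation("PHYSICIAN_CONVERSATION", rationale_codes = "HR_LT_55_FOR_BB"))
    }
    return(finish(recommendation(
      bb_step$action, bb_step$agent, bb_step$target_dose_step,
      rationale_codes = "FOURTH_LINE_BB", requires_lab_gate = FALSE
    )))
  }
  # (8) everything maximized or intolerable
  recommendation("REFER_SPECIALIST", rationale_codes = "OPTIONS_EXHAUSTED")
}

#' Pandemic risk-mitigation rewrite of a recommendation
#'
#' When monitoring blood work is unavailable and the pending step needs
#' labs (ARB/ACEI, TD, MRA): with weekly means at or above 140/90 the
#' engine substitutes a lab-free agent — CCB first, labetalol when the CCB
#' ladder is closed; below 140/90 it defers to a 2-month lifestyle trial.
#' When labs are available but constrained, new starts of lab-requiring
#' agents use the conservative dose (one step below the standard start).
#'
#' @param rec A recommendation from [next_action()].
#' @param labs_available Can the patient obtain labs?
#' @param summary The week's summary (the 140/90 split).
#' @param regimen Current regimen (for the CCB/labetalol fallback walk).
#' @param profile Patient profile.
#' @param cfg Program configuration.
#' @return The possibly rewritten `htn_recommendation`.
#' @export
apply_covid_mode <- function(rec, labs_available, summary, regimen,
                             profile, cfg = default_config()) {
  th <- cfg$thresholds
  if (!rec$action %in% c("START", "ADD", "TITRATE", "SWITCH")) return(rec)
  cls <- agent_class(rec$agent, cfg)
  if (!class_requires_labs(cls)) return(rec)

  if (isTRUE(labs_available)) {
    if (rec$action %in% c("START", "ADD", "SWITCH")) {
      rec$target_dose_step <- starting_step(rec$agent, conservative = TRUE, cfg = cfg)
      rec$rationale_codes <- c(rec$rationale_codes, "COVID_CONSERVATIVE_DOSING")
    }
    return(rec)
  }
  if (summary$mean_sbp >= th$lifestyle_sbp_max ||
      summary$mean_dbp >= th$lifestyle_dbp_max) {
    # maximize an on-board lab-free ladder first; open a new class only
    # afterwards, CCB before labetalol
    step <- NULL
    for (cls2 in c("CCB", "BB")) {
      step <- escalate_existing(cls2, regimen, goal = NULL, cfg)
      if (!is.null(step) && cls2 == "BB" && hr_too_low(summary$mean_hr, cfg)) {
        step <- NULL
      }
      if (!is.null(step)) break
    }
    if (is.null(step)) {
      for (cls2 in c("CCB", "BB")) {
        step <- open_new_class(cls2, regimen, profile, cfg)
        if (!is.null(step) && cls2 == "BB" && hr_too_low(summary$mean_hr, cfg)) {
          step <- NULL
        }
        if (!is.null(step)) break
      }
    }
    if (!is.null(step)) {
      if (step$action == "START" && length(regimen)) step$action <- "ADD"
      return(recommendation(
        step$action, step$agent, step$target_dose_step,
        rationale_codes = "COVID_NO_LABS_LAB_FREE_SUBSTITUTION",
        requires_lab_gate = FALSE
      ))
    }
    return(recommendation("PHYSICIAN_CONVERSATION",
                          rationale_codes = "COVID_NO_LABS_OPTIONS_EXHAUSTED"))
  }
  recommendation("LIFESTYLE_TRIAL",
                 rationale_codes = "COVID_NO_LABS_BELOW_140_90")
}

#' Combination-pill consolidation in maintenance
#'
#' Once doses are stable, a thiazide plus a RAAS blocker is consolidated
#' into a configured single-pill combination to aid adherence.
#'
#' @param regimen Current regimen.
#' @param as_of Evaluation date; both components must be unchanged for the
#'   configured stability period.
#' @param cfg Program configuration (combination map, stability weeks).
#' @return A `CONSOLIDATE_COMBO` recommendation naming the product, or
#'   `NULL` when nothing is combinable.
#' @export
consolidate_combo <- function(regimen, as_of = Sys.Date(),
                              cfg = default_config()) {
  as_of <- as.Date(as_of)
  stable <- vapply(regimen, function(m) {
    as.numeric(as_of - m$last_change_date) >= 7 * cfg$combo_stable_weeks
  }, logical(1))
  agents <- vapply(regimen, function(m) m$agent, character(1))
  stable_agents <- agents[stable]
  for (combo in cfg$combinations) {
    if (all(combo$components %in% stable_agents)) {
      rec <- recommendation("CONSOLIDATE_COMBO",
                            rationale_codes = c("STABLE_DOSES_ADHERENCE",
                                                combo$product))
      rec$product <- combo$product
      return(rec)
    }
  }
  NULL
}

#' Apply a recommendation to a regimen
#'
#' Bookkeeping helper used by the simulator and the command-line tools:
#' returns the regimen after a START/ADD/TITRATE/SWITCH takes effect on
#' `effective_date`. Other actions leave the regimen unchanged.
#'
#' @param regimen Current regimen.
#' @param rec An `htn_recommendation`.
#' @param effective_date Date the change takes effect.
#' @param cfg Program configuration.
#' @return The updated regimen (list of `htn_med`).
#' @export
apply_recommendation <- function(regimen, rec, effective_date,
                                 cfg = default_config()) {
  if (!rec$action %in% c("START", "ADD", "TITRATE", "SWITCH")) return(regimen)
  effective_date <- as.Date(effective_date)
  if (rec$action %in% c("START", "ADD")) {
    return(c(regimen, list(medication_state(
      rec$agent, rec$target_dose_step, start_date = effective_date, cfg = cfg
    ))))
  }
  if (rec$action == "TITRATE") {
    for (i in seq_along(regimen)) {
      if (regimen[[i]]$agent == rec$agent) {
        regimen[[i]] <- medication_state(
          rec$agent, rec$target_dose_step,
          start_date = regimen[[i]]$start_date,
          last_change_date = effective_date, cfg = cfg
        )
        return(regimen)
      }
    }
    stop("cannot titrate ", rec$agent, ": not in regimen")
  }
  # SWITCH: replace the same-slot agent (RAAS slot, or HCTZ -> chlorthalidone)
  new_cls <- agent_class(rec$agent, cfg)
  slot <- if (new_cls %in% c("ARB", "ACEI")) c("ARB", "ACEI") else new_cls
  keep <- Filter(function(m) !m$drug_class %in% slot, regimen)
  c(keep, list(medication_state(
    rec$agent, rec$target_dose_step, start_date = effective_date, cfg = cfg
  )))
}
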