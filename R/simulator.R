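# Synthetic cohort generator and closed-loop program simulator.
#
# The dose-response model is deliberately simple and invertible: each
# patient has a latent true BP; every dose step of every on-board agent
# subtracts a configured class effect (SBP mmHg per step; DBP a fixed
# fraction of it), scaled by a patient-level lognormal sensitivity.  Home
# readings add Gaussian measurement noise; office readings additionally a
# white-coat offset.  Lab analytes shift linearly per dose step of the
# lab-relevant classes, with Gaussian noise.  Chlorthalidone carries a
# step offset of 2 so the thiazide ladder HCTZ 12.5 -> 25 -> chlorthalidone
# 25 is monotone in effect.
#
# Randomness: one stream per patient (seed = master seed + patient index;
# weekly draws reseed at stream_seed + week), so editing the cohort or
# replaying one patient never perturbs another's trajectory.

#' Simulation parameters
#'
#' Validated parameter set for [generate_cohort()] and [run_program()].
#' Defaults describe a realistic referral cohort for a remote hypertension
#' program: uncontrolled baseline (150/92 mmHg true home BP on average),
#' home-device measurement noise of 6 mmHg, a mean office white-coat
#' offset of 10 mmHg, 90% schedule adherence, and moderate comorbidity
#' rates.
#'
#' @param n_patients Cohort size.
#' @param seed Master seed; identical seed and parameters reproduce the
#'   cohort and every trajectory bit-for-bit.
#' @param baseline_sbp_mean,baseline_sbp_sd,baseline_dbp_mean,baseline_dbp_sd
#'   Latent true home BP distribution, mmHg.
#' @param class_effect_sbp Named vector: SBP reduction (mmHg) per dose
#'   step for each drug class.
#' @param dbp_fraction DBP reduction as a fraction of the SBP reduction.
#' @param sensitivity_sdlog SD (log scale) of the patient-level
#'   multiplicative dose-response sensitivity (lognormal, median 1).
#' @param measurement_noise_sd Per-reading Gaussian noise, mmHg.
#' @param white_coat_offset_mean,white_coat_offset_sd Office-only additive
#'   offset, mmHg.
#' @param adherence_prob Probability each scheduled slot produces a
#'   transmitted reading.
#' @param frail_prob,dm_prob,ckd_prob,childbearing_prob Cohort mix.
#' @param lab_k_shift,lab_na_shift,lab_creat_pct Per-dose-step analyte
#'   shifts (named by class where applicable).
#' @param lab_noise_k,lab_noise_na,lab_noise_creat Analyte noise SDs.
#' @param secondary_positive_prob Probability a secondary-cause screen is
#'   reviewed positive.
#' @return A validated list of class `htn_sim_params`.
#' @export
sim_params <- function(n_patients = 50,
                       seed = 1,
                       baseline_sbp_mean = 150, baseline_sbp_sd = 12,
                       baseline_dbp_mean = 92, baseline_dbp_sd = 8,
                       class_effect_sbp = c(CCB = 5, ARB = 5, ACEI = 5,
                                            TD = 4, MRA = 5, BB = 4),
                       dbp_fraction = 0.5,
                       sensitivity_sdlog = 0.35,
                       measurement_noise_sd = 6,
                       white_coat_offset_mean = 10, white_coat_offset_sd = 6,
                       adherence_prob = 0.9,
                       frail_prob = 0.15, dm_prob = 0.25, ckd_prob = 0.12,
                       childbearing_prob = 0.08,
                       lab_k_shift = c(ARB = 0.08, ACEI = 0.08, MRA = 0.15,
                                       TD = -0.12),
                       lab_na_shift = c(TD = -0.7),
                       lab_creat_pct = c(ARB = 3, ACEI = 3, MRA = 3),
                       lab_noise_k = 0.12, lab_noise_na = 1.2,
                       lab_noise_creat = 0.04,
                       secondary_positive_prob = 0.05) {
  p <- as.list(environment())
  probs <- c(p$adherence_prob, p$frail_prob, p$dm_prob, p$ckd_prob,
             p$childbearing_prob, p$secondary_positive_prob)
  if (any(probs < 0 | probs > 1)) stop("validation error: probabilities must lie in [0, 1]")
  sds <- c(p$baseline_sbp_sd, p$baseline_dbp_sd, p$sensitivity_sdlog,
           p$measurement_noise_sd, p$white_coat_offset_sd,
           p$lab_noise_k, p$lab_noise_na, p$lab_noise_creat)
  if (any(sds < 0)) stop("validation error: SDs must be non-negative")
  if (p$n_patients < 1) stop("validation error: n_patients must be positive")
  if (!all(.drug_classes %in% names(p$class_effect_sbp))) {
    stop("validation error: class_effect_sbp must name every drug class")
  }
  structure(p, class = "htn_sim_params")
}

rnorm_or_const <- function(n, mean, sd) {
  if (sd == 0) rep(mean, n) else stats::rnorm(n, mean, sd)
}

# Dose-step effect multiplier; chlorthalidone continues the HCTZ ladder.
effective_steps <- function(med) {
  med$dose_step + if (med$agent == "chlorthalidone") 2L else 0L
}

true_bp <- function(patient, regimen, params) {
  drop_sbp <- 0
  for (m in regimen) {
    drop_sbp <- drop_sbp + params$class_effect_sbp[[m$drug_class]] *
      effective_steps(m) * patient$latent$sensitivity
  }
  c(sbp = patient$latent$true_sbp - drop_sbp,
    dbp = patient$latent$true_dbp - drop_sbp * params$dbp_fraction)
}

#' Generate a synthetic cohort
#'
#' Draws patient profiles, enrollment baseline labs and office-BP
#' histories from the configured distributions. Unless
#' `include_ineligible` is set, cohort members are eligible by
#' construction (ages inside the program band, weight under the cuff
#' limit, office BP meeting the inclusion rule).
#'
#' @param params An [sim_params()] object.
#' @param enrollment Cohort enrollment date.
#' @param include_ineligible Keep draws that would fail screening (for
#'   exercising the screening module).
#' @param cfg Program configuration.
#' @return List of patient records, each a list with `profile`,
#'   `baseline_labs`, `office_bps`, a `latent` truth block
#'   (`true_sbp`, `true_dbp`, `sensitivity`) and a per-patient
#'   `stream_seed`.
#' @export
generate_cohort <- function(params = sim_params(),
                            enrollment = as.Date("2022-01-03"),
                            include_ineligible = FALSE,
                            cfg = default_config()) {
  stopifnot(inherits(params, "htn_sim_params"))
  enrollment <- as.Date(enrollment)
  th <- cfg$thresholds
  lapply(seq_len(params$n_patients), function(i) {
    set.seed(params$seed + i)
    childbearing <- stats::runif(1) < params$childbearing_prob
    dm <- stats::runif(1) < params$dm_prob
    if (childbearing) {
      sex <- "female"
      age <- sample(max(th$age_min, if (dm) th$age_min_dm else 0, 30):
                      (th$childbearing_age_max - 1), 1)
      contraception <- FALSE
      dm <- dm && age >= th$age_min_dm
    } else {
      sex <- sample(c("male", "female"), 1)
      lo <- if (dm) th$age_min_dm + 1 else th$age_min + 4
      age <- sample(lo:th$age_max, 1)
      contraception <- sex == "female" && age < th$childbearing_age_max
    }
    ckd <- stats::runif(1) < params$ckd_prob
    egfr <- if (ckd) stats::runif(1, th$egfr_min + 2, th$egfr_raas_pathway - 1)
            else stats::runif(1, th$egfr_raas_pathway + 5, 105)
    uacr <- stats::rlnorm(1, log(8), 0.7)
    if (dm && stats::runif(1) < 0.4) uacr <- stats::rlnorm(1, log(60), 0.5)
    profile <- patient_profile(
      patient_id = sprintf("sim-%04d", i),
      age = age, sex = sex,
      weight_lb = stats::runif(1, 120, min(th$weight_limit_female,
                                           th$weight_limit_male) - 15),
      frail = stats::runif(1) < params$frail_prob,
      contraception = contraception,
      diabetes = dm,
      ascvd_risk_10yr = round(stats::runif(1, 0.02, 0.35), 3),
      medication_naive = TRUE
    )
    baseline_labs <- lab_panel(
      draw_date = enrollment - 21,
      k = round(min(5.0, max(3.6, rnorm_or_const(1, 4.2, 0.25))), 2),
      na = round(min(144, max(136, rnorm_or_const(1, 140, 1.8))), 1),
      creatinine = round(max(0.5, rnorm_or_const(1, 0.95, 0.15)), 2),
      egfr = round(egfr, 1),
      uacr = round(uacr, 1),
      role = "baseline"
    )
    latent <- list(
      true_sbp = rnorm_or_const(1, params$baseline_sbp_mean, params$baseline_sbp_sd),
      true_dbp = rnorm_or_const(1, params$baseline_dbp_mean, params$baseline_dbp_sd),
      sensitivity = if (params$sensitivity_sdlog == 0) 1 else
        stats::rlnorm(1, 0, params$sensitivity_sdlog)
    )
    latent$true_dbp <- min(latent$true_dbp, latent$true_sbp - 25)
    wc <- rnorm_or_const(3, params$white_coat_offset_mean,
                         params$white_coat_offset_sd)
    office_dates <- enrollment - c(400, 200, 45)
    sbp_off <- round(latent$true_sbp + wc +
                       rnorm_or_const(3, 0, params$measurement_noise_sd))
    dbp_off <- round(latent$true_dbp + wc * params$dbp_fraction +
                       rnorm_or_const(3, 0, params$measurement_noise_sd))
    if (!include_ineligible) {
      # guarantee the most-recent-office-reading inclusion rule fires
      sbp_off[3] <- max(sbp_off[3], th$incl_office_sbp + 1)
    }
    dbp_off <- pmin(dbp_off, sbp_off - 20)
    office_bps <- bp_stream(
      timestamp = as.POSIXct(paste(office_dates, "10:00:00"), tz = "UTC"),
      sbp = sbp_off, dbp = dbp_off, context = "office"
    )
    list(profile = profile, baseline_labs = baseline_labs,
         office_bps = office_bps, latent = latent,
         enrollment = enrollment,
         stream_seed = params$seed + 100000 + i)
  })
}

#' Simulate one monitoring week for a patient
#'
#' Emits home readings on the optimal 28-slot schedule, thinned by the
#' adherence probability. True BP follows the linear dose-step effect
#' model; each reading adds measurement noise. When `draw_labs` is set a
#' follow-up panel is emitted with drug-induced analyte shifts.
#'
#' @param patient A record from [generate_cohort()].
#' @param regimen Current regimen (list of [medication_state()]).
#' @param week_start First date of the simulated week.
#' @param week_index Week number within the program (keys the per-patient
#'   random substream).
#' @param params An [sim_params()] object.
#' @param draw_labs Emit a follow-up lab panel this week?
#' @param cfg Program configuration.
#' @return List with `readings` (data frame) and `labs`
#'   (`htn_labs` or `NULL`).
#' @export
simulate_week <- function(patient, regimen, week_start, week_index,
                          params, draw_labs = FALSE, cfg = default_config()) {
  set.seed(patient$stream_seed + week_index)
  week_start <- as.Date(week_start)
  sched <- generate_schedule("optimal", week_start, cfg)
  keep <- stats::runif(nrow(sched)) < params$adherence_prob
  sched <- sched[keep, , drop = FALSE]
  bp <- true_bp(patient, regimen, params)
  readings <- NULL
  if (nrow(sched)) {
    hhmm <- ifelse(sched$session == "am", "07:30:00", "19:30:00")
    ts <- as.POSIXct(paste(sched$date, hhmm), tz = "UTC") +
      120 * (sched$replicate - 1)
    sbp <- round(bp[["sbp"]] + rnorm_or_const(nrow(sched), 0, params$measurement_noise_sd))
    dbp <- round(bp[["dbp"]] + rnorm_or_const(nrow(sched), 0, params$measurement_noise_sd))
    dbp <- pmin(dbp, sbp - 10)
    dbp <- pmax(dbp, 30)
    hr <- round(rnorm_or_const(nrow(sched), 72, 6))
    readings <- bp_stream(ts, sbp, dbp, hr = hr, context = "home")
  }
  labs <- NULL
  if (draw_labs) {
    b <- patient$baseline_labs
    k <- b$k; na_ <- b$na; creat <- b$creatinine
    shift_for <- function(tbl, cls) {
      v <- unname(tbl[cls])
      if (length(v) != 1 || is.na(v)) 0 else v
    }
    for (m in regimen) {
      st <- effective_steps(m)
      k <- k + shift_for(params$lab_k_shift, m$drug_class) * st
      na_ <- na_ + shift_for(params$lab_na_shift, m$drug_class) * st
      creat <- creat * (1 + shift_for(params$lab_creat_pct, m$drug_class) / 100 * st)
    }
    k <- k + rnorm_or_const(1, 0, params$lab_noise_k)
    na_ <- na_ + rnorm_or_const(1, 0, params$lab_noise_na)
    creat <- creat + rnorm_or_const(1, 0, params$lab_noise_creat)
    egfr <- b$egfr * b$creatinine / creat
    labs <- lab_panel(week_start + 3, k = round(k, 2), na = round(na_, 1),
                      creatinine = round(max(0.4, creat), 2),
                      egfr = round(max(5, egfr), 1),
                      uacr = b$uacr, role = "followup")
  }
  list(readings = readings, labs = labs)
}

#' Run the closed program loop over a cohort
#'
#' Drives the full weekly cadence for every patient: simulate readings,
#' aggregate, classify the program state, run the lab gate, obtain the
#' engine's recommendation, apply it (effective the start of the next
#' week), and repeat until maintenance, referral or `max_weeks`.
#'
#' @param params An [sim_params()] object.
#' @param max_weeks Maximum simulated weeks per patient.
#' @param cohort Optional pre-built cohort (defaults to
#'   [generate_cohort()] under `params`).
#' @param covid_mode,labs_available Pandemic risk-mitigation switches
#'   passed through to the engine.
#' @param cfg Program configuration.
#' @return A data frame of class `htn_sim_log`, one row per patient-week:
#'   state, summary statistics, goal status, the action taken, the lab
#'   gate decision and alert count. Attributes `at_goal_by_week`
#'   (cohort fraction at goal per week) and `weeks_to_maintenance`
#'   (per patient; `NA` if never reached).
#' @export
run_program <- function(params = sim_params(), max_weeks = 26, cohort = NULL,
                        covid_mode = FALSE, labs_available = TRUE,
                        cfg = default_config()) {
  stopifnot(inherits(params, "htn_sim_params"))
  if (is.null(cohort)) cohort <- generate_cohort(params, cfg = cfg)
  rows <- list()
  weeks_to_maint <- rep(NA_real_, length(cohort))

  for (pi in seq_along(cohort)) {
    pat <- cohort[[pi]]
    profile <- pat$profile
    pathway <- suppressWarnings(
      assign_pathway(profile, pat$baseline_labs, covid_mode, cfg)
    )
    regimen <- list()
    state <- "enrolled_baseline"
    labs_latest <- pat$baseline_labs
    screen <- NULL
    any_change <- FALSE
    lifestyle_done <- FALSE
    lifestyle_wait <- 0L   # weeks left in a lifestyle-only trial
    pending <- NULL        # recommendation applied at next week start
    draw_labs_next <- FALSE

    for (w in seq_len(max_weeks)) {
      week_start <- pat$enrollment + 7 * (w - 1)
      if (!is.null(pending)) {
        regimen <- apply_recommendation(regimen, pending, week_start, cfg)
        any_change <- TRUE
        draw_labs_next <- isTRUE(pending$requires_lab_gate)
        pending <- NULL
      }
      sim <- simulate_week(pat, regimen, week_start, w, params,
                           draw_labs = draw_labs_next && labs_available, cfg)
      draw_labs_next <- FALSE
      if (!is.null(sim$labs)) labs_latest <- sim$labs
      summary <- weekly_average(sim$readings, week_start, cfg)
      as_of <- week_start + 7

      if (summary$sufficiency == "insufficient") {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = profile$patient_id, week = w, state = state,
          n_readings = summary$n_readings, mean_sbp = NA_real_,
          mean_dbp = NA_real_, sufficiency = summary$sufficiency,
          at_goal = NA, action = "CONTINUE_MONITORING", agent = NA_character_,
          gate = NA_character_, n_alerts = 0L, stringsAsFactors = FALSE
        )
        next
      }

      goal <- goal_status(summary, profile$frail, cfg)
      alerts <- scan_critical(sim$readings, as_of, cfg)
      last <- last_changed_med(regimen)
      weeks_since <- if (is.null(last)) Inf else
        as.numeric(as_of - last$last_change_date) / 7
      state <- classify_transition(state, summary, profile$frail,
                                   any_change, weeks_since, cfg)

      if (state %in% c("white_coat", "maintenance")) {
        if (is.na(weeks_to_maint[pi])) weeks_to_maint[pi] <- w
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = profile$patient_id, week = w, state = state,
          n_readings = summary$n_readings, mean_sbp = summary$mean_sbp,
          mean_dbp = summary$mean_dbp, sufficiency = summary$sufficiency,
          at_goal = goal$status == "at_goal", action = "MAINTENANCE",
          agent = NA_character_, gate = NA_character_,
          n_alerts = length(alerts), stringsAsFactors = FALSE
        )
        break
      }

      if (lifestyle_wait > 0L) {
        lifestyle_wait <- lifestyle_wait - 1L
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = profile$patient_id, week = w, state = state,
          n_readings = summary$n_readings, mean_sbp = summary$mean_sbp,
          mean_dbp = summary$mean_dbp, sufficiency = summary$sufficiency,
          at_goal = goal$status == "at_goal", action = "LIFESTYLE_TRIAL",
          agent = NA_character_, gate = NA_character_,
          n_alerts = length(alerts), stringsAsFactors = FALSE
        )
        next
      }
      rec <- next_action(profile, pathway, regimen, summary, goal,
                         labs = labs_latest, baseline_labs = pat$baseline_labs,
                         as_of = as_of, secondary_screen = screen,
                         labs_available = labs_available,
                         lifestyle_completed = lifestyle_done, cfg = cfg)
      if (rec$action == "LIFESTYLE_TRIAL") {
        lifestyle_done <- TRUE
        lifestyle_wait <- as.integer(
          round(cfg$thresholds$lifestyle_trial_months * 30 / 7)) - 1L
      }
      gate_decision <- NA_character_
      if (rec$requires_lab_gate) {
        gate <- check_gate(agent_class(rec$agent, cfg), labs_latest,
                           pat$baseline_labs, as_of, cfg)
        gate_decision <- gate$decision
        if (gate$decision == "BLOCK") {
          rec <- recommendation("HOLD", rationale_codes = c("LAB_GATE_BLOCK", gate$codes))
        } else if (gate$decision == "PASS_CONSERVATIVE" &&
                   rec$action %in% c("START", "ADD", "SWITCH")) {
          rec$target_dose_step <- starting_step(rec$agent, conservative = TRUE,
                                                cfg = cfg)
        }
      }
      if (rec$action == "ORDER_SECONDARY_LABS" && is.null(screen)) {
        set.seed(pat$stream_seed + 5000 + w)
        screen <- list(reviewed_positive =
                         stats::runif(1) < params$secondary_positive_prob)
      }
      if (rec$action %in% c("START", "ADD", "TITRATE", "SWITCH")) pending <- rec

      rows[[length(rows) + 1]] <- data.frame(
        patient_id = profile$patient_id, week = w, state = state,
        n_readings = summary$n_readings, mean_sbp = summary$mean_sbp,
        mean_dbp = summary$mean_dbp, sufficiency = summary$sufficiency,
        at_goal = goal$status == "at_goal", action = rec$action,
        agent = rec$agent %||% NA_character_, gate = gate_decision,
        n_alerts = length(alerts), stringsAsFactors = FALSE
      )
      if (rec$action == "REFER_SPECIALIST") {
        state <- "referred"
        break
      }
    }
  }

  log <- do.call(rbind, rows)
  # cohort fraction at goal: a patient who has entered maintenance stops
  # logging rows but stays controlled, so count them in every later week
  ids <- vapply(cohort, function(p) p$profile$patient_id, character(1))
  at_goal_by_week <- vapply(seq_len(max(log$week)), function(w) {
    rows_w <- log[log$week == w, ]
    hit <- rows_w$patient_id[!is.na(rows_w$at_goal) & rows_w$at_goal]
    silent_maint <- ids[!is.na(weeks_to_maint) & weeks_to_maint < w &
                          !ids %in% rows_w$patient_id]
    length(unique(c(hit, silent_maint))) / length(cohort)
  }, numeric(1))
  attr(log, "at_goal_by_week") <- at_goal_by_week
  attr(log, "weeks_to_maintenance") <- weeks_to_maint
  class(log) <- c("htn_sim_log", class(log))
  log
}

#' @export
print.htn_sim_log <- function(x, ...) {
  cat(sprintf("<simulation log> %d patients, %d patient-weeks\n",
              length(unique(x$patient_id)), nrow(x)))
  agw <- attr(x, "at_goal_by_week")
  cat("  fraction at goal, first -> last observed week: ",
      sprintf("%.2f -> %.2f\n", agw[1], agw[length(agw)]))
  maint <- attr(x, "weeks_to_maintenance")
  cat(sprintf("  reached maintenance: %d/%d (median %.0f weeks)\n",
              sum(!is.na(maint)), length(maint),
              stats::median(maint, na.rm = TRUE)))
  invisible(x)
}
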