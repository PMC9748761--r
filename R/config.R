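#' @keywords internal
"_PACKAGE"

# Required keys in the threshold registry.  load_config() refuses a config
# missing any of them, naming the offender.
.required_thresholds <- c(
  "goal_sbp_standard", "goal_dbp_standard", "goal_sbp_frail", "goal_dbp_frail",
  "incl_office_sbp", "incl_office_dbp", "incl_recent_months",
  "incl_lookback_months", "incl_n_readings",
  "oh_sbp_drop", "oh_dbp_drop",
  "alert_low_sbp", "alert_high_dbp", "alert_high_sbp",
  "alert_sbp_190", "alert_sbp_180", "alert_sbp_190_days", "alert_sbp_180_days",
  "alert_window_days",
  "safety_floor_sbp", "safety_floor_dbp", "hr_floor_bb",
  "outlier_sd", "optimal_readings", "optimal_days",
  "minimal_readings", "minimal_days",
  "titration_lockout_weeks", "titration_lockout_weeks_mra",
  "maintenance_confirm_weeks", "chlorthalidone_margin",
  "k_max_raas", "k_warn_raas", "k_min_td", "na_min_td", "na_warn_td",
  "k_warn_td", "egfr_min", "egfr_raas_pathway", "uacr_pathway",
  "creat_rise_pct", "k_rise_pct", "k_abs_for_rise", "egfr_drop_pct",
  "baseline_lab_max_months",
  "lifestyle_sbp_max", "lifestyle_dbp_max", "ascvd_low_risk",
  "lifestyle_trial_months",
  "post_titration_lab_window_weeks", "final_lab_window_weeks",
  "weight_limit_female", "weight_limit_male",
  "age_min", "age_min_dm", "age_max", "abpm_months", "childbearing_age_max"
)

.drug_classes <- c("CCB", "ARB", "ACEI", "TD", "MRA", "BB")
.lab_classes <- c("ARB", "ACEI", "TD", "MRA")

#' Load and validate a program configuration
#'
#' Reads the threshold registry, the per-agent dosing table, the RAAS-agent
#' policy and the combination-pill map from a YAML (or JSON) document and
#' validates every structural invariant: all required thresholds present and
#' numeric, frail goals strictly above standard goals, dose steps strictly
#' increasing within each agent, and `requires_labs` true exactly for the
#' ARB/ACEI/TD/MRA classes.
#'
#' All rule functions in the package take the resulting object as their
#' `cfg` argument (defaulting to the shipped configuration), so every
#' clinical constant can be changed without touching code.
#'
#' @param path Path to a YAML or JSON configuration file. The default is the
#'   configuration shipped with the package.
#' @return A list of class `htn_config` with elements `thresholds`,
#'   `dosing_table`, `raas_policy`, `combinations` and `combo_stable_weeks`.
#' @examples
#' cfg <- load_config()
#' cfg$thresholds$goal_sbp_standard
#' cfg$dosing_table$irbesartan$steps_mg
#' @export
load_config <- function(path = system.file("extdata", "default_config.yaml",
                                           package = "htnrms")) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$thresholds)) stop("configuration error: missing section 'thresholds'")
  if (is.null(raw$dosing_table)) stop("configuration error: missing section 'dosing_table'")

  th <- raw$thresholds
  missing_keys <- setdiff(.required_thresholds, names(th))
  if (length(missing_keys)) {
    stop("configuration error: missing threshold key(s): ",
         paste(missing_keys, collapse = ", "))
  }
  for (k in .required_thresholds) {
    if (!is.numeric(th[[k]]) || anyNA(th[[k]])) {
      stop("configuration error: threshold '", k, "' must be numeric")
    }
  }
  if (th$goal_sbp_frail <= th$goal_sbp_standard ||
      th$goal_dbp_frail <= th$goal_dbp_standard) {
    stop("validation error: frail goals must be strictly above standard goals")
  }
  if (length(th$post_titration_lab_window_weeks) != 2 ||
      diff(th$post_titration_lab_window_weeks) < 0) {
    stop("configuration error: post_titration_lab_window_weeks must be (earliest, latest)")
  }

  th$post_titration_lab_window_weeks <-
    as.numeric(unlist(th$post_titration_lab_window_weeks))

  dt <- raw$dosing_table
  for (agent in names(dt)) {
    a <- dt[[agent]]
    for (f in c("class", "steps_mg", "start_step", "requires_labs")) {
      if (is.null(a[[f]])) {
        stop("configuration error: dosing_table entry '", agent,
             "' missing field '", f, "'")
      }
    }
    if (!a$class %in% .drug_classes) {
      stop("configuration error: unknown drug class '", a$class,
           "' for agent '", agent, "'")
    }
    steps <- as.numeric(unlist(a$steps_mg)) # YAML may parse mixed int/real as list
    dt[[agent]]$steps_mg <- steps
    dt[[agent]]$start_step <- as.integer(a$start_step)
    if (length(steps) < 1 || any(diff(steps) <= 0)) {
      stop("validation error: dose steps for '", agent,
           "' must be strictly increasing in mg")
    }
    if (a$start_step < 1 || a$start_step > length(steps)) {
      stop("validation error: start_step for '", agent, "' out of range")
    }
    must_gate <- a$class %in% .lab_classes
    if (!identical(isTRUE(a$requires_labs), must_gate)) {
      stop("validation error: requires_labs for '", agent,
           "' must be ", must_gate, " for class ", a$class)
    }
  }

  cfg <- list(
    thresholds = th,
    dosing_table = dt,
    raas_policy = raw$raas_policy,
    combinations = raw$combinations,
    combo_stable_weeks = raw$combo_stable_weeks %||% 4
  )
  class(cfg) <- "htn_config"
  cfg
}

.cfg_cache <- new.env(parent = emptyenv())

#' Shipped default configuration (cached)
#'
#' @return The `htn_config` object from the package's default YAML.
#' @export
default_config <- function() {
  if (is.null(.cfg_cache$cfg)) .cfg_cache$cfg <- load_config()
  .cfg_cache$cfg
}

#' Serialize a configuration back to YAML
#'
#' Round-trips with [load_config()]: writing and re-reading yields an
#' identical registry.
#'
#' @param cfg An `htn_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "htn_config"))
  out <- unclass(cfg)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.htn_config <- function(x, ...) {
  cat("<htn_config>\n")
  cat("  thresholds:", length(x$thresholds), "keys\n")
  cat("  agents:", paste(names(x$dosing_table), collapse = ", "), "\n")
  invisible(x)
}

# -- dosing-table helpers ----------------------------------------------------

agent_info <- function(agent, cfg = default_config()) {
  a <- cfg$dosing_table[[agent]]
  if (is.null(a)) stop("unknown agent '", agent, "' (not in dosing table)")
  a
}

agent_class <- function(agent, cfg = default_config()) {
  agent_info(agent, cfg)$class
}

n_dose_steps <- function(agent, cfg = default_config()) {
  length(agent_info(agent, cfg)$steps_mg)
}

#' Starting dose step for an agent
#'
#' @param agent Agent name (a key of the dosing table).
#' @param conservative If `TRUE`, the conservative start: one step below the
#'   standard starting step, floored at the lowest step. Used for frail
#'   patients and in pandemic risk-mitigation mode.
#' @param cfg Program configuration.
#' @return Integer dose-step index (1-based).
#' @export
starting_step <- function(agent, conservative = FALSE, cfg = default_config()) {
  a <- agent_info(agent, cfg)
  if (conservative) max(1L, as.integer(a$start_step) - 1L) else as.integer(a$start_step)
}

class_requires_labs <- function(drug_class) {
  drug_class %in% .lab_classes
}

agents_of_class <- function(drug_class, cfg = default_config()) {
  names(Filter(function(a) a$class %in% drug_class, cfg$dosing_table))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
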