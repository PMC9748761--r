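# File readers/writers, weekly-report rendering and audit logging.
# All readers validate row by row and report malformed rows with their
# line numbers rather than failing wholesale.

#' Read a BP stream from CSV
#'
#' Expects columns `timestamp,sbp,dbp,hr,context` (`hr` and `context`
#' optional; ISO-8601 timestamps, interpreted as UTC). Rows violating
#' `sbp > dbp > 0` or with unparseable timestamps are dropped with a
#' warning naming their line numbers; the rejected rows are attached as
#' attribute `"rejected"`.
#'
#' @param path CSV file path.
#' @return Data frame of validated readings (possibly empty).
#' @export
read_bp_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(raw)) {
    warning("empty BP file: ", path)
    return(bp_stream(character(), numeric(), numeric())[0, ])
  }
  for (col in c("timestamp", "sbp", "dbp")) {
    if (!col %in% names(raw)) stop("BP CSV missing column '", col, "'")
  }
  if (!"hr" %in% names(raw)) raw$hr <- NA_real_
  if (!"context" %in% names(raw)) raw$context <- "home"
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  sbp <- suppressWarnings(as.numeric(raw$sbp))
  dbp <- suppressWarnings(as.numeric(raw$dbp))
  bad <- is.na(ts) | is.na(sbp) | is.na(dbp) | !(sbp > dbp & dbp > 0)
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed BP row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
  }
  out <- data.frame(timestamp = ts[!bad], sbp = sbp[!bad], dbp = dbp[!bad],
                    hr = suppressWarnings(as.numeric(raw$hr))[!bad],
                    context = as.character(raw$context)[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- which(bad)
  out
}

#' Read lab panels from CSV
#'
#' Expects columns `draw_date,k,na,creatinine,egfr,uacr,role`.
#'
#' @param path CSV file path.
#' @return List of [lab_panel()] records, ordered by draw date.
#' @export
read_labs_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw <- raw[order(as.Date(raw$draw_date)), , drop = FALSE]
  lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    lab_panel(r$draw_date, r$k, r$na, r$creatinine, r$egfr,
              uacr = if ("uacr" %in% names(r)) r$uacr else NA_real_,
              role = if ("role" %in% names(r)) r$role else "followup")
  })
}

#' Read a patient profile from JSON
#'
#' @param path JSON file whose keys match [patient_profile()] arguments.
#' @return An `htn_profile`.
#' @export
read_profile_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(patient_profile, args)
}

#' Render a weekly report
#'
#' Combines the weekly summary, goal status, engine recommendation and
#' program-level lab warnings into a human-readable markdown report. An
#' insufficient week reports a continued-monitoring request and carries no
#' recommendation.
#'
#' @param summary An [weekly_average()] result.
#' @param goal An [goal_status()] result, or `NULL` for an insufficient
#'   week.
#' @param recommendation The engine recommendation, or `NULL`.
#' @param warnings Character vector from [program_warnings()].
#' @param patient_id Patient identifier printed on the report.
#' @return Character vector of markdown lines.
#' @export
render_weekly_report <- function(summary, goal = NULL, recommendation = NULL,
                                 warnings = character(), patient_id = "") {
  lines <- c(
    sprintf("# Weekly BP report — %s", patient_id),
    sprintf("Window starting %s: %d readings over %d days (%s).",
            format(summary$window_start), summary$n_readings,
            summary$distinct_days, summary$sufficiency)
  )
  if (summary$sufficiency == "insufficient") {
    return(c(lines, "Insufficient readings this week: continue monitoring; no recommendation issued."))
  }
  lines <- c(lines, sprintf(
    "Mean BP %.1f/%.1f mmHg (excluded as outliers: %d SBP, %d DBP values).",
    summary$mean_sbp, summary$mean_dbp,
    summary$n_excluded_sbp, summary$n_excluded_dbp))
  if (!is.null(goal)) {
    lines <- c(lines, sprintf("Goal (%d/%d): **%s**%s", goal$goal_sbp,
                              goal$goal_dbp, goal$status,
                              if (goal$safety_floor_flag) " — SAFETY FLOOR" else ""))
  }
  if (!is.null(recommendation)) {
    rec_line <- if (recommendation$action == "HOLD" &&
                    "AT_GOAL_PENDING_LABS" %in% recommendation$rationale_codes) {
      "Recommendation: HOLD — controlled; maintenance pending labs as appropriate."
    } else {
      sprintf("Recommendation: %s%s [%s]", recommendation$action,
              if (!is.null(recommendation$agent))
                sprintf(" %s to step %d", recommendation$agent,
                        recommendation$target_dose_step) else "",
              paste(recommendation$rationale_codes, collapse = ", "))
    }
    lines <- c(lines, rec_line)
    if (recommendation$requires_lab_gate) {
      lines <- c(lines, "Lab gate required before prescribing.")
    }
  }
  if (length(warnings)) {
    lines <- c(lines, paste("Lab warnings:", paste(warnings, collapse = ", ")))
  }
  lines
}

#' Create an audit record
#'
#' One machine-readable line per engine decision, gate result, alert or
#' state transition, suitable for an append-only JSON-lines log.
#'
#' @param patient_id Patient identifier.
#' @param module,operation Where the decision was made.
#' @param inputs Any list of inputs; stored as a digest (their serialized
#'   length and names) rather than raw PHI.
#' @param decision The decision value (character).
#' @param rationale_codes Machine-readable codes.
#' @param timestamp Record timestamp.
#' @return A list of class `htn_audit`.
#' @export
audit_record <- function(patient_id, module, operation, inputs = list(),
                         decision, rationale_codes = character(),
                         timestamp = Sys.time()) {
  structure(list(
    timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    patient_id = patient_id, module = module, operation = operation,
    inputs_digest = sprintf("fields:%s", paste(names(inputs), collapse = ",")),
    decision = decision,
    rationale_codes = as.character(rationale_codes)
  ), class = "htn_audit")
}

#' Append audit records to a JSON-lines log
#'
#' @param records A single [audit_record()] or list of them.
#' @param path Log file path (created if absent).
#' @return `path`, invisibly.
#' @export
append_audit <- function(records, path) {
  if (inherits(records, "htn_audit")) records <- list(records)
  con <- file(path, open = "a")
  on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(unclass(r), auto_unbox = TRUE), con)
  }
  invisible(path)
}
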