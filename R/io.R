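#' Write a session log to disk
#'
#' Serializes an `asa_session` as plain-text files in a directory: the
#' event log as JSON, the BrAC/infusion series and assessments as CSV.
#'
#' @param session an `asa_session`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "asa_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(subject = session$subject,
               session_index = session$session_index,
               drug_level = session$drug_level,
               cwfa = session$cwfa, cwfs = session$cwfs,
               peak_brac = session$peak_brac, mean_brac = session$mean_brac,
               saline_ml_total = session$saline_ml_total)
  jsonlite::write_json(list(meta = meta, events = session$events),
                       file.path(dir, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(session$brac, file.path(dir, "brac.csv"), row.names = FALSE)
  write.csv(session$assessments, file.path(dir, "assessments.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a session log from disk
#'
#' Restores the fields written by [write_session()]. The result carries the
#' class `asa_session` and supports [cumulative_work()] and the analysis
#' functions (the live simulation internals - trajectory, final PK state -
#' are not round-tripped).
#'
#' @param dir directory written by [write_session()].
#' @return An `asa_session`.
#' @export
read_session <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "events.json"),
                           simplifyVector = TRUE)
  out <- c(j$meta, list(
    events = as.data.frame(j$events),
    brac = read.csv(file.path(dir, "brac.csv")),
    assessments = read.csv(file.path(dir, "assessments.csv"))))
  class(out) <- "asa_session"
  out
}

#' Read a structured configuration file
#'
#' Reads a YAML or JSON configuration and instantiates the matching
#' configuration objects. Recognised top-level sections: `subject`
#' (passed to [subject_profile()]), `pk` ([pk_params()]), `agent`
#' ([agent_params()]), `schedule` ([work_schedule()] fields `n1`, `ratio`,
#' `mean_trial_s`, or empty for [calibrate_schedule()]), `cat`
#' ([cat_config()]), `session` ([session_config()]), `cohort`
#' ([cohort_config()]). Missing sections keep package defaults.
#'
#' @param path file path; extension `.yaml`/`.yml` or `.json`.
#' @return A named list of configuration objects (elements `subject`,
#'   `pk`, `agent`, `schedule`, `cat`, `session`, `cohort` as present).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    .stopf("unsupported config extension '%s'", ext))
  out <- list()
  if (!is.null(raw$subject)) out$subject <- do.call(subject_profile, raw$subject)
  if (!is.null(raw$pk)) out$pk <- do.call(pk_params, raw$pk)
  if (!is.null(raw$agent)) out$agent <- do.call(agent_params, raw$agent)
  if (!is.null(raw$schedule))
    out$schedule <- if (length(raw$schedule)) do.call(work_schedule, raw$schedule)
                    else calibrate_schedule()
  if (!is.null(raw$cat)) out$cat <- do.call(cat_config, raw$cat)
  if (!is.null(raw$session)) out$session <- do.call(session_config, raw$session)
  if (!is.null(raw$cohort)) out$cohort <- do.call(cohort_config, raw$cohort)
  out
}

#' Write trial outputs
#'
#' Writes the per-subject endpoint table as CSV and the group statistics as
#' JSON.
#'
#' @param trial an `asa_trial` from [simulate_trial()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "asa_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(trial$endpoints, file.path(dir, "endpoints.csv"),
            row.names = FALSE)
  st <- trial$stats
  flat <- list(
    control = st$control, treated = st$treated,
    full = st$full[c("t", "df", "p", "d", "lo", "hi")],
    ascending = st$ascending[c("t", "df", "p", "d", "lo", "hi")],
    plateau = st$plateau[c("t", "df", "p", "d", "lo", "hi")],
    blood_level_correlation = st$blood_level_correlation)
  jsonlite::write_json(flat, file.path(dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
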