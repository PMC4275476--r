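compute_totals <- function(attempts) {
  n <- length(attempts)
  successes <- sum(vapply(attempts, function(a) isTRUE(a$success), logical(1)))
  errs <- list()
  for (a in attempts) {
    for (e in a$error_events) {
      errs[[e$id]] <- (if (is.null(errs[[e$id]])) 0L else errs[[e$id]]) + 1L
    }
  }
  durations <- vapply(attempts, function(a) a$duration, numeric(1))
  list(attempts = n, successes = successes,
       total_errors = if (length(errs)) sum(unlist(errs)) else 0L,
       errors_by_fault = errs,
       durations = durations,
       mean_duration = if (any(!is.na(durations)))
         mean(durations, na.rm = TRUE) else NA_real_)
}

#' Summarize attempts into a session report
#'
#' Aggregates per-attempt results into the statistics collected for the
#' therapist: attempts, successes, error counts by fault, and per-attempt
#' and mean durations, together with a snapshot of the threshold
#' configuration in force. Durations appear only here — they are never
#' part of patient-facing feedback.
#'
#' @param attempts List of `attempt_result` objects (possibly empty).
#' @param config The [threshold_config] used during the session.
#' @param session_id,patient_id Opaque identifier strings.
#' @return An object of class `session_report`.
#' @export
summarize <- function(attempts, config, session_id = "session-1",
                      patient_id = "anonymous") {
  structure(list(session_id = session_id, patient_id = patient_id,
                 attempts = attempts, totals = compute_totals(attempts),
                 config_snapshot = config),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  tt <- x$totals
  cat(sprintf("<session_report> %s / %s: %d attempts, %d successes, %d errors, mean duration %s s\n",
              x$session_id, x$patient_id, tt$attempts, tt$successes,
              tt$total_errors,
              ifelse(is.na(tt$mean_duration), "NA",
                     sprintf("%.2f", tt$mean_duration))))
  invisible(x)
}

attempt_to_list <- function(a) {
  list(index = a$index, complete = a$complete, success = a$success,
       error_events = lapply(a$error_events, function(e)
         list(id = e$id, start_t = e$start_t, end_t = e$end_t)),
       duration = a$duration, conclusions = as.list(a$conclusions))
}

attempt_from_list <- function(x) {
  structure(list(
    index = as.integer(x$index), complete = isTRUE(x$complete),
    success = isTRUE(x$success),
    error_events = lapply(x$error_events, function(e)
      list(id = e$id, start_t = as.numeric(e$start_t),
           end_t = as.numeric(e$end_t))),
    duration = if (is.null(x$duration)) NA_real_ else as.numeric(x$duration),
    conclusions = as.character(unlist(x$conclusions))
  ), class = "attempt_result")
}

config_to_list <- function(config) {
  list(strictness = config$strictness, overrides = config$overrides,
       included_parts = as.list(config$included_parts),
       balance_epsilon = config$balance_epsilon,
       debounce_frames = config$debounce_frames)
}

config_from_list <- function(x) {
  threshold_config(strictness = x$strictness,
                   overrides = x$overrides,
                   included_parts = as.character(unlist(x$included_parts)),
                   balance_epsilon = x$balance_epsilon,
                   debounce_frames = x$debounce_frames)
}

#' Serialize a session report to JSON
#'
#' @param report A [summarize()] result.
#' @param path Optional output file.
#' @return JSON text (invisibly when `path` given).
#' @seealso [parse_report()]
#' @export
serialize_report <- function(report, path = NULL) {
  body <- list(session_id = report$session_id,
               patient_id = report$patient_id,
               attempts = lapply(report$attempts, attempt_to_list),
               totals = report$totals,
               config_snapshot = config_to_list(report$config_snapshot))
  txt <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                          null = "null", na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse and verify a session report
#'
#' Lossless inverse of [serialize_report()]. The stored totals are
#' recomputed from the attempt list on load; any mismatch is an integrity
#' error (tampered or corrupted report).
#'
#' @param text JSON text, or a path to a JSON file.
#' @return A [session_report][summarize].
#' @export
parse_report <- function(text) {
  if (length(text) == 1L && !grepl("^\\s*\\{", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  x <- jsonlite::fromJSON(paste(text, collapse = "\n"),
                          simplifyVector = FALSE)
  attempts <- lapply(x$attempts, attempt_from_list)
  report <- summarize(attempts, config_from_list(x$config_snapshot),
                      session_id = x$session_id, patient_id = x$patient_id)
  stored <- x$totals
  fresh <- report$totals
  same_num <- function(a, b) {
    a <- unlist(a); b <- unlist(b)
    (length(a) == length(b)) &&
      all(is.na(a) == is.na(b)) &&
      all(abs(as.numeric(a[!is.na(a)]) - as.numeric(b[!is.na(b)])) < 1e-9)
  }
  ok <- stored$attempts == fresh$attempts &&
    stored$successes == fresh$successes &&
    stored$total_errors == fresh$total_errors &&
    same_num(stored$errors_by_fault, fresh$errors_by_fault) &&
    same_num(stored$durations, fresh$durations) &&
    same_num(stored$mean_duration, fresh$mean_duration)
  if (!ok) {
    stop("report integrity error: stored totals do not match the attempts")
  }
  report
}

#' Describe a therapist parameter update
#'
#' The adaptation loop: after reviewing session statistics the therapist
#' adjusts the monitoring parameters to the patient's progress. Only the
#' named fields change; `NULL` fields are left untouched.
#'
#' @param strictness,overrides,included_parts,balance_epsilon,debounce_frames
#'   New values for the corresponding [threshold_config()] fields, or
#'   `NULL` to keep the current ones.
#' @param spec_fields Named list of [exercise_spec()] fields to change.
#' @param note Free-text rationale for the change.
#' @return An object of class `therapist_update`.
#' @export
therapist_update <- function(strictness = NULL, overrides = NULL,
                             included_parts = NULL, balance_epsilon = NULL,
                             debounce_frames = NULL, spec_fields = list(),
                             note = "") {
  structure(list(strictness = strictness, overrides = overrides,
                 included_parts = included_parts,
                 balance_epsilon = balance_epsilon,
                 debounce_frames = debounce_frames,
                 spec_fields = spec_fields, note = note),
            class = "therapist_update")
}

#' Apply a therapist update to configuration and exercise spec
#'
#' Validates the result: an update that would produce a non-positive
#' strictness, empty included parts, or an inconsistent course geometry
#' is rejected with an error. The change is logged with a timestamp.
#'
#' @param config Current [threshold_config].
#' @param spec Current [exercise_spec].
#' @param update A [therapist_update].
#' @param time Timestamp recorded in the change log (injectable for
#'   reproducible tests).
#' @return List with `config`, `spec` and a one-row `log` data frame
#'   (`time`, `fields`, `note`).
#' @export
apply_update <- function(config, spec, update, time = Sys.time()) {
  stopifnot(inherits(update, "therapist_update"))
  pick <- function(new, old) if (is.null(new)) old else new
  changed <- names(Filter(Negate(is.null),
                          update[c("strictness", "overrides",
                                   "included_parts", "balance_epsilon",
                                   "debounce_frames")]))
  new_config <- threshold_config(
    strictness = pick(update$strictness, config$strictness),
    overrides = pick(update$overrides, config$overrides),
    included_parts = pick(update$included_parts, config$included_parts),
    balance_epsilon = pick(update$balance_epsilon, config$balance_epsilon),
    debounce_frames = pick(update$debounce_frames, config$debounce_frames))
  sf <- update$spec_fields
  if (length(sf) > 0L) {
    args <- unclass(spec)
    bad <- setdiff(names(sf), names(args))
    if (length(bad)) stop("unknown exercise_spec field: ",
                          paste(bad, collapse = ", "))
    args[names(sf)] <- sf
    # keep geometry consistent when only the length or the start moves
    if (!is.null(sf$course_length) && is.null(sf$finish_z)) {
      args$finish_z <- args$start_z + args$course_length
    }
    new_spec <- do.call(exercise_spec, args)
    changed <- c(changed, paste0("spec.", names(sf)))
  } else {
    new_spec <- spec
  }
  list(config = new_config, spec = new_spec,
       log = data.frame(time = as.character(time),
                        fields = paste(changed, collapse = ","),
                        note = update$note))
}

# ---- template / config / spec JSON files ------------------------------------

#' Read and write posture templates, threshold configs and exercise specs
#'
#' JSON document formats for the therapist-tunable surface (schemas under
#' `inst/schemas/`). Each `write_*` is the canonical inverse of the
#' corresponding `read_*`.
#'
#' @param x Object to write.
#' @param path File path.
#' @return The read object, or (for writers) the JSON text invisibly.
#' @name config_io
NULL

#' @rdname config_io
#' @export
write_template <- function(x, path = NULL) {
  body <- list(name = x$name, rules = lapply(x$rules, unclass))
  txt <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname config_io
#' @export
read_template <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  posture_template(x$name, lapply(x$rules, function(r)
    alignment_rule(r$id, r$joint_a, r$joint_b, r$axis, r$base_epsilon,
                   r$body_part)))
}

#' @rdname config_io
#' @export
write_threshold_config <- function(x, path = NULL) {
  txt <- jsonlite::toJSON(config_to_list(x), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname config_io
#' @export
read_threshold_config <- function(path) {
  config_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' @rdname config_io
#' @export
write_exercise_spec <- function(x, path = NULL) {
  txt <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname config_io
#' @export
read_exercise_spec <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  exercise_spec(course_length = x$course_length, start_z = x$start_z,
                finish_z = x$finish_z,
                corridor_center_x = x$corridor_center_x,
                corridor_half_width = x$corridor_half_width,
                hold_seconds = x$hold_seconds,
                start_zone_tolerance = x$start_zone_tolerance,
                direction = x$direction)
}
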