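#' Define the walking-exercise specification
#'
#' Geometry and timing of the three-step exercise: hold an upright posture
#' at the start line, walk a straight course, and hold again at the finish
#' line.
#'
#' @param course_length Start-to-finish distance in meters (default the
#'   standard 5 m course).
#' @param start_z Longitudinal coordinate of the start line (m).
#' @param finish_z Longitudinal coordinate of the finish line (m); must be
#'   `start_z + course_length`.
#' @param corridor_center_x Lateral center of the walking corridor (m).
#' @param corridor_half_width Half-width of the corridor (m); crossing the
#'   lines is a margin-touch fault.
#' @param hold_seconds Seconds of continuous compliant upright posture
#'   required at start and finish.
#' @param start_zone_tolerance Longitudinal tolerance (m) for "at the
#'   line" during the holds.
#' @param direction `"forward"` (z increasing) or `"backward"` (mirrored
#'   z mapping).
#' @return An object of class `exercise_spec`.
#' @export
exercise_spec <- function(course_length = 5.0, start_z = 0.0,
                          finish_z = start_z + course_length,
                          corridor_center_x = 0.0,
                          corridor_half_width = 0.25,
                          hold_seconds = 3.0,
                          start_zone_tolerance = 0.15,
                          direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (course_length <= 0) stop("course_length must be > 0")
  if (corridor_half_width <= 0) stop("corridor_half_width must be > 0")
  if (hold_seconds <= 0) stop("hold_seconds must be > 0")
  if (start_zone_tolerance <= 0) stop("start_zone_tolerance must be > 0")
  if (abs((finish_z - start_z) - course_length) > 1e-9) {
    stop("finish_z - start_z must equal course_length")
  }
  structure(list(course_length = course_length, start_z = start_z,
                 finish_z = finish_z,
                 corridor_center_x = corridor_center_x,
                 corridor_half_width = corridor_half_width,
                 hold_seconds = hold_seconds,
                 start_zone_tolerance = start_zone_tolerance,
                 direction = direction),
            class = "exercise_spec")
}

feedback_event <- function(t, kind, severity, payload = list()) {
  structure(list(t = t, kind = kind, severity = severity, payload = payload),
            class = "feedback_event")
}

# longitudinal pelvis coordinate in exercise direction (backward courses
# mirror z about the course midpoint, so all downstream logic is shared)
course_z <- function(frame, spec) {
  z <- unname(frame$joints["HipCenter", "z"])
  if (spec$direction == "backward") spec$start_z + spec$finish_z - z else z
}

#' Start a new exercise attempt
#'
#' Initializes the three-step state machine at step 1 (the start-line
#' hold). The step variable only ever increases within an attempt: 1
#' (start hold) to 2 (walk) to 3 (finish hold), after which the attempt is
#' terminal.
#'
#' @param spec An [exercise_spec].
#' @param template A [posture_template] for the holds (its shoulder/trunk
#'   subset is used during the walk).
#' @param config A [threshold_config].
#' @return An object of class `exercise_state`.
#' @export
new_session <- function(spec, template, config) {
  stopifnot(inherits(spec, "exercise_spec"),
            inherits(template, "posture_template"),
            inherits(config, "threshold_config"))
  structure(list(
    step = 1L, terminal = FALSE, started = FALSE,
    hold_elapsed = 0, last_t = NA_real_, last_compliant = FALSE,
    progress = 0, last_course_z = NA_real_,
    active = list(),          # fault id -> debounce tracker
    error_events = list(),    # closed maximal violating runs
    events_log = list(),
    attempt_start_t = NA_real_, attempt_end_t = NA_real_,
    transitions = data.frame(step = integer(), t = numeric(),
                             hip_z = numeric())
  ), class = "exercise_state")
}

# one debounce tracker step for a fault id; a fault event fires on the
# debounce_frames-th consecutive violating frame and a maximal run counts
# as a single error
fault_step <- function(active, id, violating, t, debounce) {
  tr <- active[[id]]
  confirmed_now <- FALSE
  closed <- NULL
  if (violating) {
    if (is.null(tr)) {
      tr <- list(count = 1L, start_t = t, last_t = t, confirmed = FALSE)
    } else {
      tr$count <- tr$count + 1L
      tr$last_t <- t
    }
    if (!tr$confirmed && tr$count >= debounce) {
      tr$confirmed <- TRUE
      confirmed_now <- TRUE
    }
    active[[id]] <- tr
  } else if (!is.null(tr)) {
    if (tr$confirmed) {
      closed <- list(id = id, start_t = tr$start_t, end_t = tr$last_t)
    }
    active[[id]] <- NULL
  }
  list(active = active, confirmed_now = confirmed_now, closed = closed)
}

close_open_runs <- function(state) {
  for (id in names(state$active)) {
    tr <- state$active[[id]]
    if (tr$confirmed) {
      state$error_events[[length(state$error_events) + 1L]] <-
        list(id = id, start_t = tr$start_t, end_t = tr$last_t)
    }
  }
  state$active <- list()
  state
}

fault_message <- function(id) {
  switch(id,
    balance = "Keep your balance: do not lean to the side while walking.",
    margin = "Stay between the walking lines.",
    posture = "Keep the upright posture: align the highlighted joints.",
    paste0("Correct fault '", id, "'."))
}

#' Corridor (walking-lines) check
#'
#' Tests whether the walker's support (both ankles and the pelvis) stays
#' inside the lateral corridor. The corridor is inclusive: a point exactly
#' on a line is not a touch.
#'
#' @param frame A valid [skeleton_frame].
#' @param spec An [exercise_spec].
#' @return `"left"`, `"right"` (the crossed boundary) or `"none"`.
#' @export
corridor_check <- function(frame, spec) {
  xs <- frame$joints[c("AnkleLeft", "AnkleRight", "HipCenter"), "x"]
  left <- spec$corridor_center_x - spec$corridor_half_width
  right <- spec$corridor_center_x + spec$corridor_half_width
  over_l <- left - min(xs)
  over_r <- max(xs) - right
  if (over_l <= 0 && over_r <= 0) return("none")
  if (over_l >= over_r) "left" else "right"
}

hold_compliant <- function(frame, line_z, spec, template, config) {
  zz <- course_z(frame, spec)
  if (abs(zz - line_z) > spec$start_zone_tolerance) return(FALSE)
  evaluate_posture(frame, template, config)$correct
}

#' Advance the exercise state machine by one frame
#'
#' Step 1 requires the pelvis within the start zone and a continuous
#' upright hold; any non-compliant frame resets the hold clock. Step 2
#' monitors per frame: lateral balance (debounced `balance_alert` plus a
#' `corrective_arrow` pointing to the side the patient must move toward),
#' the shoulder/trunk posture subset (`misaligned_bones`), and the
#' corridor (`margin_touch`); pelvis advance drives the progress fraction
#' and the finish-line crossing enters step 3. Step 3 repeats the hold at
#' the finish line and terminates the attempt with a `congratulation`
#' (error-free) or a `conclusion` event listing the corrections.
#'
#' Faults are debounced: an event fires only after `debounce_frames`
#' consecutive violating frames, and one maximal violating run is one
#' error. Event payloads never contain timing totals (duration is reported
#' only on the therapist side).
#'
#' @param object An [exercise_state][new_session].
#' @param frame The next [skeleton_frame]; its timestamp must not precede
#'   the previous one.
#' @param spec,template,config As in [new_session()].
#' @param ... Unused (S3 signature compatibility).
#' @return List with elements `state` (updated) and `events` (the
#'   feedback events emitted for this frame, possibly empty).
#' @importFrom stats update
#' @export
update.exercise_state <- function(object, frame, spec, template, config,
                                  ...) {
  state <- object
  viol <- validate_frame(frame)
  if (length(viol) > 0L) {
    stop("invalid frame at t=", frame$t, ": ", paste(viol, collapse = "; "))
  }
  if (!is.na(state$last_t) && frame$t < state$last_t) {
    stop("frame timestamp decreased")
  }
  if (state$terminal) {
    return(list(state = state, events = list()))
  }
  events <- list()
  emit <- function(kind, severity, payload = list()) {
    events[[length(events) + 1L]] <<- feedback_event(frame$t, kind, severity,
                                                     payload)
  }
  if (!state$started) {
    state$started <- TRUE
    emit("task_instruction", "informational",
         list(step = 1L, message = "Stand still upright at the start line."))
  }
  t <- frame$t
  zz <- course_z(frame, spec)
  debounce <- config$debounce_frames

  if (state$step == 1L) {
    ok <- hold_compliant(frame, spec$start_z, spec, template, config)
    if (ok) {
      if (is.na(state$attempt_start_t)) state$attempt_start_t <- t
      state$hold_elapsed <- if (state$last_compliant)
        state$hold_elapsed + (t - state$last_t) else 0
      if (state$hold_elapsed >= spec$hold_seconds) {
        state$step <- 2L
        state$hold_elapsed <- 0
        state$last_compliant <- FALSE
        state$transitions <- rbind(state$transitions,
          data.frame(step = 2L, t = t, hip_z = unname(frame$joints["HipCenter", "z"])))
        emit("task_instruction", "informational",
             list(step = 2L, message = "Walk straight to the finish line."))
      } else {
        state$last_compliant <- TRUE
      }
    } else {
      state$hold_elapsed <- 0
      state$last_compliant <- FALSE
    }
  } else if (state$step == 2L) {
    state$progress <- max(state$progress,
                          min(1, max(0, (zz - spec$start_z) / spec$course_length)))
    # balance
    bl <- balance_level(frame, config)
    fs <- fault_step(state$active, "balance", bl$alert, t, debounce)
    state$active <- fs$active
    if (!is.null(fs$closed)) {
      state$error_events[[length(state$error_events) + 1L]] <- fs$closed
    }
    if (fs$confirmed_now) {
      emit("balance_alert", "intrusive", list(side = bl$side))
      emit("corrective_arrow", "informational",
           list(side = if (bl$side == "left") "right" else "left"))
    }
    # walking posture subset
    wt <- walking_template(template)
    has_rules <- any(vapply(wt$rules,
                            function(r) r$body_part %in% config$included_parts,
                            logical(1)))
    if (has_rules) {
      pv <- evaluate_posture(frame, wt, config)
      fs <- fault_step(state$active, "posture", !pv$correct, t, debounce)
      state$active <- fs$active
      if (!is.null(fs$closed)) {
        state$error_events[[length(state$error_events) + 1L]] <- fs$closed
      }
      if (fs$confirmed_now) {
        emit("misaligned_bones", "informational",
             list(joints = pv$misaligned_joints))
      }
    }
    # corridor
    cc <- corridor_check(frame, spec)
    fs <- fault_step(state$active, "margin", cc != "none", t, debounce)
    state$active <- fs$active
    if (!is.null(fs$closed)) {
      state$error_events[[length(state$error_events) + 1L]] <- fs$closed
    }
    if (fs$confirmed_now) {
      emit("margin_touch", "intrusive", list(side = cc))
    }
    if (zz >= spec$finish_z) {
      state$step <- 3L
      state$progress <- 1
      state$hold_elapsed <- 0
      state$last_compliant <- FALSE
      state$transitions <- rbind(state$transitions,
        data.frame(step = 3L, t = t, hip_z = unname(frame$joints["HipCenter", "z"])))
      emit("task_instruction", "informational",
           list(step = 3L, message = "Stop and hold the upright posture."))
    }
  } else if (state$step == 3L) {
    ok <- hold_compliant(frame, spec$finish_z, spec, template, config)
    if (ok) {
      state$hold_elapsed <- if (state$last_compliant)
        state$hold_elapsed + (t - state$last_t) else 0
      state$last_compliant <- TRUE
      if (state$hold_elapsed >= spec$hold_seconds) {
        state$terminal <- TRUE
        state$attempt_end_t <- t
        state <- close_open_runs(state)
        if (length(state$error_events) == 0L) {
          emit("congratulation", "informational",
               list(message = "Exercise completed correctly. Congratulations!"))
        } else {
          ids <- unique(vapply(state$error_events, `[[`, character(1), "id"))
          emit("conclusion", "informational",
               list(messages = vapply(ids, fault_message, character(1),
                                      USE.NAMES = FALSE)))
        }
      }
    } else {
      state$hold_elapsed <- 0
      state$last_compliant <- FALSE
    }
  }
  state$last_t <- t
  state$last_course_z <- zz
  state$events_log <- c(state$events_log, events)
  list(state = state, events = events)
}

#' Progress fraction of the current attempt
#'
#' Fraction of the course covered by the pelvis: 0 before the walk begins,
#' clamped to \[0, 1\], and 1 at or past the finish line.
#'
#' @param state An [exercise_state][new_session].
#' @return Numeric fraction in \[0, 1\].
#' @export
progress <- function(state) {
  state$progress
}

#' Summarize a finished attempt
#'
#' Converts a terminal exercise state into the attempt record reported to
#' the therapist: success (no error runs), the error runs themselves, the
#' attempt duration, and the post-attempt conclusions (one correction per
#' distinct fault, ordered by first occurrence; empty when the attempt
#' was error-free).
#'
#' @param state A terminal [exercise_state][new_session] (see
#'   [run_attempt()] for incomplete streams).
#' @param index Attempt number within the session (>= 1).
#' @param allow_incomplete If `TRUE`, a non-terminal state yields a result
#'   flagged `complete = FALSE` instead of an error.
#' @return An object of class `attempt_result`.
#' @export
finalize_attempt <- function(state, index = 1L, allow_incomplete = FALSE) {
  if (!state$terminal) {
    if (!allow_incomplete) {
      stop("attempt is not finished; cannot finalize")
    }
    state <- close_open_runs(state)
  }
  errs <- state$error_events
  ord <- order(vapply(errs, `[[`, numeric(1), "start_t"))
  errs <- errs[ord]
  ids <- unique(vapply(errs, `[[`, character(1), "id"))
  complete <- state$terminal
  duration <- if (complete) state$attempt_end_t - state$attempt_start_t
              else NA_real_
  structure(list(
    index = as.integer(index),
    complete = complete,
    success = complete && length(errs) == 0L,
    error_events = errs,
    duration = duration,
    conclusions = if (length(ids)) vapply(ids, fault_message, character(1),
                                          USE.NAMES = FALSE) else character()
  ), class = "attempt_result")
}

#' Run one attempt over a whole stream
#'
#' Batch driver: folds [update()] over the frames of a stream and
#' finalizes. Equivalent, event for event, to feeding the frames
#' incrementally. A stream that ends before the attempt terminates yields
#' a result flagged incomplete (`complete = FALSE`); that is data, not an
#' error.
#'
#' @param stream A [skeleton_stream].
#' @param spec,template,config As in [new_session()].
#' @param index Attempt number for the result.
#' @return List with `result` (an `attempt_result`), `events` (all
#'   feedback events in order) and `state` (the final machine state).
#' @export
run_attempt <- function(stream, spec = exercise_spec(),
                        template = upright_template(),
                        config = threshold_config(), index = 1L) {
  state <- new_session(spec, template, config)
  for (fr in stream$frames) {
    state <- update(state, fr, spec, template, config)$state
    if (state$terminal) break
  }
  list(result = finalize_attempt(state, index = index,
                                 allow_incomplete = TRUE),
       events = state$events_log,
       state = state)
}

#' Split a recording into attempts at rest gaps
#'
#' A session recording may contain several attempts separated by rest
#' pauses where capture stops; a gap between consecutive frame timestamps
#' longer than `rest_gap` delimits attempts.
#'
#' @param stream A [skeleton_stream].
#' @param rest_gap Minimum gap in seconds that separates attempts.
#' @return List of [skeleton_stream] segments (>= 1).
#' @export
split_attempts <- function(stream, rest_gap = 5.0) {
  ts <- frame_times(stream)
  cuts <- which(diff(ts) > rest_gap)
  if (length(cuts) == 0L) return(list(stream))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(ts))
  lapply(seq_along(starts), function(i) {
    skeleton_stream(stream$frames[seq.int(starts[i], ends[i])],
                    fps = stream$meta$fps,
                    subject_height = stream$meta$subject_height,
                    source = stream$meta$source)
  })
}

#' Serialize feedback events as JSON lines
#'
#' @param events List of feedback events (as emitted by [update()] /
#'   [run_attempt()]).
#' @param path Optional output file.
#' @return Character vector of JSONL lines (invisibly when `path` given).
#' @export
write_events <- function(events, path = NULL) {
  out <- vapply(events, function(e) {
    jsonlite::toJSON(list(t = e$t, kind = e$kind, severity = e$severity,
                          payload = e$payload),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
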