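clean_run <- function(seed = 1L, ...) {
  params <- walker_params(noise_sd = 0, seed = seed, ...)
  spec <- exercise_spec()
  stream <- walking_stream(params, spec)
  list(res = run_attempt(stream, spec), stream = stream, spec = spec)
}

test_that("a clean simulated attempt walks the step variable 1 -> 2 -> 3", {
  out <- clean_run()
  res <- out$res
  expect_identical(res$state$step, 3L)
  expect_true(res$state$terminal)
  expect_true(res$result$success)
  expect_length(res$result$error_events, 0L)
  expect_identical(res$state$transitions$step, c(2L, 3L))
  kinds <- vapply(res$events, `[[`, character(1), "kind")
  expect_identical(kinds[length(kinds)], "congratulation")
  expect_equal(progress(res$state), 1)
})

test_that("a subject who never reaches the start zone stays in step 1", {
  spec <- exercise_spec()
  stream <- standing_frames(walker_params(noise_sd = 0, seed = 2L),
                            duration = 5, z = 2.0) # mid-course, not at start
  res <- run_attempt(stream, spec)
  expect_identical(res$state$step, 1L)
  expect_false(res$result$complete)
  expect_false(res$result$success)
  expect_true(is.na(res$result$duration))
})

test_that("session construction validates its inputs", {
  expect_error(exercise_spec(course_length = 0), "course_length")
  expect_error(exercise_spec(finish_z = 3), "finish_z")
  st <- new_session(exercise_spec(), upright_template(), threshold_config())
  expect_identical(st$step, 1L)
  expect_equal(progress(st), 0)
  expect_length(st$active, 0L)
  expect_error(finalize_attempt(st), "not finished")
})

test_that("corridor check names the crossed boundary, inclusive on the lines", {
  spec <- exercise_spec(corridor_half_width = 0.25)
  fr <- ideal_frame(z = 2.5)
  expect_identical(corridor_check(fr, spec), "none")
  right <- fr
  right$joints[, "x"] <- right$joints[, "x"] + 0.30
  expect_identical(corridor_check(right, spec), "right")
  left <- fr
  left$joints[, "x"] <- left$joints[, "x"] - 0.30
  expect_identical(corridor_check(left, spec), "left")
  # exactly on the boundary is not a touch: widest support point at +0.25
  ank <- max(fr$joints[c("AnkleLeft", "AnkleRight", "HipCenter"), "x"])
  edge <- fr
  edge$joints[, "x"] <- edge$joints[, "x"] + (0.25 - ank)
  expect_identical(corridor_check(edge, spec), "none")
})

test_that("progress tracks the pelvis fraction of the course, clamped", {
  spec <- exercise_spec()
  tpl <- upright_template()
  cfg <- threshold_config()
  s2 <- enter_step2(spec, tpl, cfg)
  state <- s2$state
  expect_equal(progress(state), 0)
  mid <- ideal_frame(z = 2.5, t = s2$t)
  state <- update(state, mid, spec, tpl, cfg)$state
  expect_equal(progress(state), 0.5)
  fin <- ideal_frame(z = 5.4, t = s2$t + 1 / 30)
  state <- update(state, fin, spec, tpl, cfg)$state
  expect_identical(state$step, 3L)
  expect_equal(progress(state), 1)
})

test_that("faults are debounced into maximal runs, matching an RLE oracle", {
  spec <- exercise_spec()
  tpl <- upright_template()
  set.seed(314)
  for (rep in seq_len(8L)) {
    debounce <- sample(2:6, 1L)
    cfg <- threshold_config(debounce_frames = debounce)
    s2 <- enter_step2(spec, tpl, cfg)
    state <- s2$state
    t <- s2$t
    mask <- stats::runif(60L) < 0.4
    for (viol in c(mask, rep(FALSE, debounce + 2L))) {
      fr <- ideal_frame(z = 2.5, t = t)
      if (viol) fr <- lower_shoulder(fr, "left", 0.2)
      state <- update(state, fr, spec, tpl, cfg)$state
      t <- t + 1 / 30
    }
    runs <- rle_runs(mask, debounce)
    got <- Filter(function(e) e$id == "balance", state$error_events)
    expect_length(got, nrow(runs))
    alerts <- Filter(function(e) e$kind == "balance_alert", state$events_log)
    expect_length(alerts, nrow(runs))
  }
})

test_that("an injected lean yields one balance run covering the fault window", {
  spec <- exercise_spec()
  cfg <- threshold_config()
  stream <- walking_stream(walker_params(noise_sd = 0, seed = 4L), spec)
  window <- c(5, 8) # inside the walk phase
  faulty <- inject_fault(stream, "lean", window, magnitude = 10)
  res <- run_attempt(faulty, spec, config = cfg)
  bal <- Filter(function(e) e$id == "balance", res$result$error_events)
  expect_length(bal, 1L)
  slack <- cfg$debounce_frames / 30 + 1e-9
  expect_gte(bal[[1L]]$start_t, window[1L] - slack)
  expect_lte(bal[[1L]]$start_t, window[1L] + slack)
  expect_gte(bal[[1L]]$end_t, window[2L] - slack)
  expect_lte(bal[[1L]]$end_t, window[2L] + slack)
  # positive lean lowers the right shoulder; correction points left
  arrows <- Filter(function(e) e$kind == "corrective_arrow", res$events)
  expect_length(arrows, 1L)
  expect_identical(arrows[[1L]]$payload$side, "left")
  expect_false(res$result$success)
  expect_gt(length(res$result$conclusions), 0L)
})

test_that("balance alert threshold is sharp against the simulator", {
  spec <- exercise_spec()
  cfg <- threshold_config(balance_epsilon = 0.1)
  for (v in c(0.080, 0.095, 0.105, 0.130)) {
    stream <- walking_stream(walker_params(noise_sd = 0, seed = 5L), spec)
    faulty <- inject_fault(stream, "lean", c(5, 8),
                           magnitude = asin(v) * 180 / pi)
    res <- run_attempt(faulty, spec, config = cfg)
    ids <- vapply(res$result$error_events, `[[`, character(1), "id")
    expect_identical("balance" %in% ids, v > 0.1)
  }
})

test_that("batch monitoring equals incremental folding and is deterministic", {
  spec <- exercise_spec()
  tpl <- upright_template()
  cfg <- threshold_config()
  stream <- inject_fault(
    walking_stream(walker_params(noise_sd = 0.002, seed = 6L), spec),
    "drift", c(6, 7.5), magnitude = 0.35)
  batch <- run_attempt(stream, spec, tpl, cfg)
  state <- new_session(spec, tpl, cfg)
  for (fr in stream$frames) {
    state <- update(state, fr, spec, tpl, cfg)$state
    if (state$terminal) break
  }
  manual <- finalize_attempt(state, allow_incomplete = TRUE)
  expect_equal(batch$result, manual)
  expect_identical(write_events(batch$events),
                   write_events(state$events_log))
  again <- run_attempt(stream, spec, tpl, cfg)
  expect_identical(write_events(batch$events), write_events(again$events))
})

test_that("drift off the line raises a margin touch on the drift side", {
  spec <- exercise_spec()
  stream <- walking_stream(
    walker_params(noise_sd = 0, sway_amp = 0, drift_rate = 0.1, seed = 7L),
    spec)
  res <- run_attempt(stream, spec)
  touches <- Filter(function(e) e$kind == "margin_touch", res$events)
  expect_gt(length(touches), 0L)
  expect_identical(touches[[1L]]$payload$side, "right")
  ids <- vapply(res$result$error_events, `[[`, character(1), "id")
  expect_true("margin" %in% ids)
})

test_that("attempt duration spans the attempt window and stays therapist-only", {
  out <- clean_run()
  res <- out$res
  ts <- frame_times(out$stream)
  # clean walker is compliant from the first frame to termination
  expect_equal(res$result$duration,
               res$state$attempt_end_t - ts[1L], tolerance = 1e-9)
  span <- res$state$attempt_end_t - res$state$attempt_start_t
  expect_equal(res$result$duration, span, tolerance = 1 / 30 + 1e-9)
  # hidden timing: no feedback payload carries durations or clocks
  for (e in res$events) {
    expect_false(any(grepl("duration|elapsed|time", names(e$payload))))
  }
})

test_that("success means exactly zero error runs, on clean and faulty fixtures", {
  clean <- clean_run(seed = 8L)$res
  expect_true(clean$result$success)
  expect_length(clean$result$error_events, 0L)
  spec <- exercise_spec()
  faulty <- run_attempt(
    inject_fault(walking_stream(walker_params(noise_sd = 0, seed = 9L), spec),
                 "lean", c(5, 7), magnitude = 12),
    spec)
  expect_false(faulty$result$success)
  expect_gt(length(faulty$result$error_events), 0L)
})

test_that("one-frame streams yield an incomplete attempt, not an error", {
  spec <- exercise_spec()
  stream <- skeleton_stream(list(ideal_frame(z = 0, t = 0)), fps = 30)
  res <- run_attempt(stream, spec)
  expect_false(res$result$complete)
  expect_false(res$result$success)
})

test_that("two disjoint fault windows produce two error runs", {
  spec <- exercise_spec()
  stream <- walking_stream(walker_params(noise_sd = 0, seed = 10L), spec)
  faulty <- inject_fault(inject_fault(stream, "lean", c(4.5, 6),
                                      magnitude = 10),
                         "lean", c(9, 10.5), magnitude = 10)
  res <- run_attempt(faulty, spec)
  bal <- Filter(function(e) e$id == "balance", res$result$error_events)
  expect_length(bal, 2L)
})
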