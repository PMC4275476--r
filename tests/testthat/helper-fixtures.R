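# shared fixtures: all inputs are generated in code, no stored data

# one ideal standing frame (noiseless, no impairment) at a given pelvis z
ideal_frame <- function(height = 1.70, z = 0, t = 0) {
  stream <- standing_frames(
    walker_params(height = height, noise_sd = 0, sway_amp = 0, seed = 1L),
    duration = 0.01, z = z)
  fr <- stream$frames[[1L]]
  fr$t <- t
  fr
}

# a frame with uniformly random joint positions (not a plausible body;
# used for brute-force verdict oracles)
random_frame <- function(t = 0) {
  j <- matrix(stats::runif(60L, -2, 2), nrow = 20L,
              dimnames = list(JOINT_NAMES, c("x", "y", "z")))
  structure(list(t = t, joints = j), class = "skeleton_frame")
}

random_rule <- function(id = "r") {
  ab <- sample(JOINT_NAMES, 2L)
  alignment_rule(id, ab[1L], ab[2L], sample(c("x", "y"), 1L),
                 stats::runif(1L, 0.01, 0.5), "any")
}

# left-right mirror of a frame: negate x and swap paired joints
mirror_frame <- function(frame) {
  j <- frame$joints
  j[, "x"] <- -j[, "x"]
  nm <- rownames(j)
  swapped <- nm
  swapped[grepl("Left$", nm)] <- sub("Left$", "Right", nm[grepl("Left$", nm)])
  swapped[grepl("Right$", nm)] <- sub("Right$", "Left", nm[grepl("Right$", nm)])
  rownames(j) <- swapped
  frame$joints <- j[rownames(frame$joints), , drop = FALSE]
  frame
}

# lower one shoulder by delta meters (balance impairment on a single frame)
lower_shoulder <- function(frame, side = c("left", "right"), delta) {
  side <- match.arg(side)
  joint <- if (side == "left") "ShoulderLeft" else "ShoulderRight"
  frame$joints[joint, "y"] <- frame$joints[joint, "y"] - delta
  frame
}

# drive a fresh session through the start hold into step 2; returns the
# state and the time of the next frame to feed
enter_step2 <- function(spec = exercise_spec(), template = upright_template(),
                        config = threshold_config()) {
  state <- new_session(spec, template, config)
  t <- 0
  repeat {
    fr <- ideal_frame(z = spec$start_z, t = t)
    state <- update(state, fr, spec, template, config)$state
    t <- t + 1 / 30
    if (state$step == 2L) break
    if (t > 30) stop("never entered step 2")
  }
  list(state = state, t = t)
}

# the upright rules whose ideal coordinate difference is exactly zero in
# the exercise stance (the others, e.g. hand-at-hip, have small nonzero
# anatomical offsets)
zero_diff_template <- function() {
  posture_template("zero_diff", Filter(function(r) {
    r$id %in% c("shoulders_level", "hips_level", "back_straight",
                "foot_left_under_shoulder", "foot_right_under_shoulder")
  }, upright_template()$rules))
}

# independent run-length-encoding oracle: maximal violating runs of
# length >= debounce, as (start index, end index) pairs
rle_runs <- function(mask, debounce) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= debounce
  data.frame(start = starts[keep], end = ends[keep])
}
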