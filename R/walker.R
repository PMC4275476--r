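#' Synthetic walker parameters
#'
#' Parameters of the seeded articulated-walker generator used to emulate
#' a person standing and walking the straight course in front of a depth
#' sensor, with controllable impairments (lateral lean, drift off the
#' line, postural sway) and sensor jitter.
#'
#' @param height Subject height in meters.
#' @param speed Walking speed in m/s (impaired gait is slow; default
#'   0.5 m/s covers a 5 m course in 10 s).
#' @param fps Capture rate in frames/second.
#' @param lean_deg Constant lateral lean in degrees; positive lowers the
#'   right shoulder. May also be a function of time (seconds) returning
#'   degrees, for piecewise profiles.
#' @param drift_rate Lateral drift in meters per meter of advance along
#'   the course.
#' @param sway_amp,sway_freq Amplitude (m) and frequency (Hz) of the
#'   sinusoidal lateral body sway.
#' @param arm_swing_amp Longitudinal arm-swing amplitude (m) during the
#'   walk phase (left/right antiphase).
#' @param arm_swing_freq Arm-swing frequency in Hz.
#' @param noise_sd Standard deviation (m) of iid Gaussian jitter added to
#'   every coordinate; default 3 mm, typical of consumer depth sensors.
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   stream bitwise after canonical serialization.
#' @return An object of class `walker_params`.
#' @export
walker_params <- function(height = 1.70, speed = 0.5, fps = 30,
                          lean_deg = 0, drift_rate = 0,
                          sway_amp = 0.02, sway_freq = 0.6,
                          arm_swing_amp = 0.05, arm_swing_freq = 0.9,
                          noise_sd = 0.003, seed = 1L) {
  if (height <= 0 || speed <= 0 || fps <= 0) {
    stop("height, speed and fps must be > 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(height = height, speed = speed, fps = fps,
                 lean_deg = lean_deg, drift_rate = drift_rate,
                 sway_amp = sway_amp, sway_freq = sway_freq,
                 arm_swing_amp = arm_swing_amp,
                 arm_swing_freq = arm_swing_freq,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "walker_params")
}

.walker_cache <- new.env(parent = emptyenv())

#' Anthropometric segment model
#'
#' Joint offsets of the idealized standing skeleton as fixed fractions of
#' subject height: `x_frac` lateral (negative = subject's left), `y_frac`
#' vertical from the floor, `z_frac` longitudinal. Left/right symmetric;
#' ankles are placed under the shoulders, which is the stance the
#' exercise requires. Shipped as a plain-text table in
#' `inst/extdata/anthropometry.tsv`.
#'
#' @return Data frame with columns `joint`, `x_frac`, `y_frac`, `z_frac`,
#'   one row per joint in canonical order.
#' @export
anthropometric_model <- function() {
  if (is.null(.walker_cache$anthro)) {
    path <- system.file("extdata", "anthropometry.tsv", package = "rehabwalk")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stopifnot(identical(tab$joint, JOINT_NAMES))
    .walker_cache$anthro <- tab
  }
  .walker_cache$anthro
}

# base standing pose: 20 x 3 matrix in meters for a subject of given height
base_pose <- function(height) {
  a <- anthropometric_model()
  m <- cbind(x = a$x_frac, y = a$y_frac, z = a$z_frac) * height
  rownames(m) <- a$joint
  m
}

# vertical-shear lateral lean about the pelvis: joints above the pelvis
# drop (rise) by their lateral lever arm times sin(lean); x is unchanged,
# so the shoulder-width-normalized balance level recovers sin(lean) exactly
apply_lean <- function(joints, lean_deg) {
  if (lean_deg == 0) return(joints)
  s <- sin(lean_deg * pi / 180)
  hip <- joints["HipCenter", ]
  above <- joints[, "y"] > hip["y"]
  joints[above, "y"] <- joints[above, "y"] -
    (joints[above, "x"] - hip["x"]) * s
  joints
}

run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# shared frame builder: schedule has columns t, z (pelvis longitudinal
# position), walking (logical), walk_t (seconds since walk start)
build_frames <- function(params, schedule, start_z) {
  pose0 <- base_pose(params$height)
  arm_rows <- c("ElbowLeft", "WristLeft", "HandLeft")
  arm_rows_r <- c("ElbowRight", "WristRight", "HandRight")
  lean_fun <- if (is.function(params$lean_deg)) params$lean_deg
              else function(t) params$lean_deg
  n <- nrow(schedule)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    t <- schedule$t[i]
    j <- pose0
    j[, "z"] <- j[, "z"] + schedule$z[i]
    # lateral sway (whole body) + drift proportional to advance
    dx <- params$sway_amp * sin(2 * pi * params$sway_freq * t) +
      params$drift_rate * (schedule$z[i] - start_z)
    j[, "x"] <- j[, "x"] + dx
    if (schedule$walking[i] && params$arm_swing_amp > 0) {
      dz <- params$arm_swing_amp *
        sin(2 * pi * params$arm_swing_freq * schedule$walk_t[i])
      j[arm_rows, "z"] <- j[arm_rows, "z"] + dz
      j[arm_rows_r, "z"] <- j[arm_rows_r, "z"] - dz
    }
    j <- apply_lean(j, lean_fun(t))
    if (params$noise_sd > 0) {
      # fixed joint-major draw order for reproducibility
      j <- j + matrix(stats::rnorm(60L, 0, params$noise_sd),
                      nrow = 20L, byrow = TRUE)
    }
    frames[[i]] <- structure(list(t = t, joints = j),
                             class = "skeleton_frame")
  }
  frames
}

#' Generate a stationary standing stream
#'
#' The walker stands still in the upright exercise posture at a given
#' longitudinal position, with the configured lean, sway and noise.
#' Seeded and reproducible.
#'
#' @param params A [walker_params].
#' @param duration Seconds of standing (> 0).
#' @param z Longitudinal pelvis position in meters (e.g. the start line).
#' @return A [skeleton_stream].
#' @export
standing_frames <- function(params, duration, z = 0) {
  if (duration <= 0) stop("duration must be > 0")
  n <- max(1L, floor(duration * params$fps) + 1L)
  sched <- data.frame(t = (seq_len(n) - 1L) / params$fps, z = z,
                      walking = FALSE, walk_t = 0)
  frames <- run_seeded(params$seed, build_frames(params, sched, z))
  skeleton_stream(frames, fps = params$fps,
                  subject_height = params$height,
                  source = "rehabwalk synthetic walker (standing)")
}

#' Generate a full simulated exercise stream
#'
#' Three concatenated phases matching the exercise: a standing hold at
#' the start line (hold time plus half a second of slack), a straight
#' walk along the course at constant speed with sinusoidal arm swing and
#' sway, and a standing hold at the finish line. Lean, drift and noise
#' are applied as configured. Seeded and reproducible.
#'
#' @param params A [walker_params].
#' @param spec An [exercise_spec].
#' @return A [skeleton_stream] spanning the whole attempt.
#' @export
walking_stream <- function(params, spec = exercise_spec()) {
  fps <- params$fps
  walk_dur <- spec$course_length / params$speed
  if (walk_dur * fps < 2) {
    stop("speed too high: fewer than 2 frames span the course")
  }
  hold_dur <- spec$hold_seconds + 0.5
  t1 <- hold_dur                 # walk starts
  t2 <- t1 + walk_dur            # walk ends
  total <- t2 + spec$hold_seconds + 0.6
  n <- floor(total * fps) + 1L
  t <- (seq_len(n) - 1L) / fps
  z <- ifelse(t < t1, spec$start_z,
              pmin(spec$finish_z, spec$start_z + params$speed * (t - t1)))
  walking <- t >= t1 & t < t2
  sched <- data.frame(t = t, z = z, walking = walking,
                      walk_t = ifelse(walking, t - t1, 0))
  frames <- run_seeded(params$seed,
                       build_frames(params, sched, spec$start_z))
  skeleton_stream(frames, fps = fps, subject_height = params$height,
                  source = "rehabwalk synthetic walker (full attempt)")
}

#' Inject a labeled fault into a stream
#'
#' Modifies frames inside a time window to create a ground-truth labeled
#' fixture: a lateral-lean step change (degrees), a lateral drift offset
#' (meters), or a freeze (joints held at their last pre-window
#' positions). The ground-truth window is attached as attribute
#' `fault_truth`.
#'
#' @param stream A [skeleton_stream].
#' @param fault One of `"lean"`, `"drift"`, `"freeze"`.
#' @param window Numeric `c(t0, t1)` inside the stream span, t0 < t1.
#' @param magnitude Fault size: degrees for lean, meters for drift,
#'   ignored for freeze.
#' @return The modified [skeleton_stream] with attribute `fault_truth`
#'   (list with `fault`, `window`, `magnitude`).
#' @export
inject_fault <- function(stream, fault = c("lean", "drift", "freeze"),
                         window, magnitude = 0) {
  fault <- match.arg(fault)
  ts <- frame_times(stream)
  if (length(window) != 2L || window[2L] <= window[1L]) {
    stop("window must be c(t0, t1) with t0 < t1")
  }
  if (window[1L] > ts[length(ts)] || window[2L] < ts[1L]) {
    stop("window lies outside the stream span")
  }
  idx <- which(ts >= window[1L] & ts <= window[2L])
  if (fault == "freeze") {
    ref <- if (min(idx) > 1L) stream$frames[[min(idx) - 1L]]$joints
           else stream$frames[[1L]]$joints
    for (i in idx) stream$frames[[i]]$joints <- ref
  } else if (magnitude != 0) {
    for (i in idx) {
      j <- stream$frames[[i]]$joints
      if (fault == "lean") {
        j <- apply_lean(j, magnitude)
      } else {
        j[, "x"] <- j[, "x"] + magnitude
      }
      stream$frames[[i]]$joints <- j
    }
  }
  attr(stream, "fault_truth") <- list(fault = fault, window = window,
                                      magnitude = magnitude)
  stream
}
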