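#' The 20 tracked joints of a skeleton frame
#'
#' Names of the twenty body joints every skeleton frame must carry, in
#' canonical order. The taxonomy follows first-generation consumer depth
#' sensors (Kinect-v1 style): a central chain (pelvis, spine, shoulder
#' centre, head) plus left/right arm and leg chains.
#'
#' @format Character vector of length 20.
#' @export
JOINT_NAMES <- c(
  "HipCenter", "Spine", "ShoulderCenter", "Head",
  "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
  "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
  "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
  "HipRight", "KneeRight", "AnkleRight", "FootRight"
)

AXES <- c("x", "y", "z")

#' Construct a skeleton frame
#'
#' A frame is one time-stamped snapshot of the 20 tracked joint positions.
#' Coordinates are in meters in the sensor frame: x lateral (positive toward
#' the patient's right as seen by the sensor), y vertical (up positive),
#' z longitudinal, increasing along the walking direction away from the
#' sensor.
#'
#' @param t Time in seconds since stream start (non-negative scalar).
#' @param joints Numeric 20 x 3 matrix of joint positions in meters; row
#'   names must be exactly [JOINT_NAMES], columns `x`, `y`, `z`.
#' @return An object of class `skeleton_frame`.
#' @seealso [validate_frame()], [parse_stream()]
#' @export
skeleton_frame <- function(t, joints) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("frame timestamp must be a single finite non-negative number")
  }
  joints <- as.matrix(joints)
  if (is.null(rownames(joints))) {
    stop("joint matrix must have joint names as row names")
  }
  joints <- joints[, seq_len(3L), drop = FALSE]
  colnames(joints) <- AXES
  fr <- structure(list(t = as.numeric(t), joints = joints),
                  class = "skeleton_frame")
  viol <- validate_frame(fr)
  if (length(viol) > 0L) {
    stop("invalid skeleton frame: ", paste(viol, collapse = "; "))
  }
  # canonical joint order so frames compare field-for-field
  fr$joints <- fr$joints[JOINT_NAMES, , drop = FALSE]
  fr
}

#' Validate a skeleton frame
#'
#' Checks the frame invariants and reports violations without raising:
#' all 20 joints present exactly once, no extraneous joints, all
#' coordinates finite.
#'
#' @param frame A `skeleton_frame` (or anything frame-shaped).
#' @return Character vector of human-readable violation descriptors;
#'   empty when the frame is valid.
#' @export
validate_frame <- function(frame) {
  viol <- character()
  joints <- frame$joints
  if (!is.matrix(joints) || !is.numeric(joints)) {
    return("joints must be a numeric matrix")
  }
  nm <- rownames(joints)
  missing <- setdiff(JOINT_NAMES, nm)
  if (length(missing) > 0L) {
    viol <- c(viol, paste0("missing joint ", missing))
  }
  extra <- setdiff(nm, JOINT_NAMES)
  if (length(extra) > 0L) {
    viol <- c(viol, paste0("unknown joint ", extra))
  }
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0L) {
    viol <- c(viol, paste0("duplicate joint ", dup))
  }
  if (ncol(joints) != 3L) {
    viol <- c(viol, "each joint needs exactly 3 coordinates (x, y, z)")
  } else {
    bad <- which(!is.finite(joints), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      viol <- c(viol, sprintf("non-finite coordinate at %s.%s",
                              rownames(joints)[bad[, 1L]], AXES[bad[, 2L]]))
    }
  }
  if (!is.null(frame$t) &&
      (!is.numeric(frame$t) || !is.finite(frame$t) || frame$t < 0)) {
    viol <- c(viol, "timestamp must be finite and non-negative")
  }
  viol
}

#' Construct a skeleton stream
#'
#' An ordered, strictly time-increasing sequence of skeleton frames plus
#' stream metadata.
#'
#' @param frames List of [skeleton_frame] objects; non-empty, timestamps
#'   strictly increasing.
#' @param fps Nominal capture rate in frames/second (all monitoring logic
#'   uses the per-frame timestamps; fps is informational).
#' @param subject_height Optional subject height in meters, informational
#'   only (the posture checks are height-independent).
#' @param source Free-text provenance of the stream.
#' @return An object of class `skeleton_stream` with elements `meta` and
#'   `frames`.
#' @export
skeleton_stream <- function(frames, fps = NA_real_,
                            subject_height = NA_real_, source = "") {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("a skeleton stream must contain at least one frame")
  }
  ts <- vapply(frames, function(f) f$t, numeric(1))
  if (any(diff(ts) <= 0)) {
    i <- which(diff(ts) <= 0)[1L]
    stop(sprintf("timestamps must be strictly increasing (frame %d: t=%g after t=%g)",
                 i + 1L, ts[i + 1L], ts[i]))
  }
  if (!is.na(fps) && fps <= 0) stop("fps must be > 0")
  structure(
    list(meta = list(fps = fps, subject_height = subject_height,
                     source = source),
         frames = frames),
    class = "skeleton_stream")
}

#' @export
length.skeleton_stream <- function(x) length(x$frames)

#' @export
print.skeleton_stream <- function(x, ...) {
  ts <- frame_times(x)
  cat(sprintf("<skeleton_stream> %d frames, t = [%.3f, %.3f] s, fps = %s\n",
              length(x$frames), ts[1L], ts[length(ts)],
              ifelse(is.na(x$meta$fps), "?", format(x$meta$fps))))
  invisible(x)
}

#' Frame timestamps of a stream
#' @param stream A `skeleton_stream`.
#' @return Numeric vector of frame times in seconds.
#' @export
frame_times <- function(stream) {
  vapply(stream$frames, function(f) f$t, numeric(1))
}

#' Extract one joint's trajectory from a stream
#'
#' @param stream A `skeleton_stream`.
#' @param joint A joint name from [JOINT_NAMES].
#' @return Data frame with columns `t`, `x`, `y`, `z`.
#' @export
joint_trajectory <- function(stream, joint) {
  joint <- match.arg(joint, JOINT_NAMES)
  pos <- t(vapply(stream$frames, function(f) f$joints[joint, ], numeric(3)))
  data.frame(t = frame_times(stream), x = pos[, 1L], y = pos[, 2L],
             z = pos[, 3L])
}

# ---- stream dialect (line-delimited JSON) -----------------------------------
#
# Line 1: header object {"fps": ..., "subject_height": ..., "source": ...}
# Lines 2..n+1: one frame object per line:
#   {"t": <seconds>, "joints": {"HipCenter": [x, y, z], ...}}
# Coordinates are serialized with 9 decimal digits, which is the canonical
# formatting the round-trip guarantee refers to.

#' Parse a skeleton stream from its line-delimited JSON dialect
#'
#' The dialect is one metadata header object on the first line followed by
#' one frame object per line (see `inst/schemas/stream.schema.json`). Every
#' frame must carry all 20 joints with finite coordinates and timestamps
#' must be strictly increasing; violations are reported with the offending
#' line number.
#'
#' @param lines Character vector of dialect lines, or a length-1 path to a
#'   file containing them.
#' @return A validated [skeleton_stream].
#' @seealso [write_stream()]
#' @export
parse_stream <- function(lines) {
  if (length(lines) == 1L && !grepl("^\\s*\\{", lines) && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("stream must contain a header line and at least one frame line")
  }
  meta <- tryCatch(jsonlite::fromJSON(lines[[1L]]),
                   error = function(e) stop("line 1: invalid header JSON: ",
                                            conditionMessage(e)))
  frames <- vector("list", length(lines) - 1L)
  for (i in seq.int(2L, length(lines))) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) stop(sprintf("line %d: invalid JSON: %s",
                                                     i, conditionMessage(e))))
    if (is.null(rec$t) || is.null(rec$joints)) {
      stop(sprintf("line %d: frame record needs fields 't' and 'joints'", i))
    }
    jn <- names(rec$joints)
    if (anyDuplicated(jn)) {
      stop(sprintf("line %d: duplicate joint %s", i, jn[duplicated(jn)][1L]))
    }
    coords <- do.call(rbind, lapply(rec$joints, as.numeric))
    fr <- structure(list(t = as.numeric(rec$t), joints = coords),
                    class = "skeleton_frame")
    viol <- validate_frame(fr)
    if (length(viol) > 0L) {
      stop(sprintf("line %d: %s", i, paste(viol, collapse = "; ")))
    }
    fr$joints <- fr$joints[JOINT_NAMES, , drop = FALSE]
    colnames(fr$joints) <- AXES
    frames[[i - 1L]] <- fr
  }
  ts <- vapply(frames, function(f) f$t, numeric(1))
  if (any(diff(ts) <= 0)) {
    i <- which(diff(ts) <= 0)[1L]
    stop(sprintf("line %d: non-monotone timestamp (t=%g after t=%g)",
                 i + 2L, ts[i + 1L], ts[i]))
  }
  skeleton_stream(frames,
                  fps = if (is.null(meta$fps)) NA_real_ else as.numeric(meta$fps),
                  subject_height = if (is.null(meta$subject_height)) NA_real_
                                   else as.numeric(meta$subject_height),
                  source = if (is.null(meta$source)) "" else as.character(meta$source))
}

fmt_num <- function(x) {
  # canonical number formatting: fixed 9 decimals, trailing zeros trimmed
  s <- sprintf("%.9f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", ".0", s)
}

#' Serialize a skeleton stream to its line-delimited JSON dialect
#'
#' Canonical inverse of [parse_stream()]: fixed joint order, coordinates at
#' nine decimal digits, so identical streams serialize to identical bytes.
#'
#' @param stream A valid [skeleton_stream].
#' @param path Optional file path; when given, lines are written there.
#' @return Character vector of dialect lines (invisibly when `path` given).
#' @export
write_stream <- function(stream, path = NULL) {
  if (!inherits(stream, "skeleton_stream")) stop("not a skeleton_stream")
  if (length(stream$frames) == 0L) stop("cannot serialize an empty stream")
  meta <- stream$meta
  header <- sprintf('{"fps": %s, "subject_height": %s, "source": %s}',
                    ifelse(is.na(meta$fps), "null", fmt_num(meta$fps)),
                    ifelse(is.na(meta$subject_height), "null",
                           fmt_num(meta$subject_height)),
                    jsonlite::toJSON(meta$source, auto_unbox = TRUE))
  recs <- vapply(stream$frames, function(fr) {
    j <- fr$joints[JOINT_NAMES, , drop = FALSE]
    body <- paste(sprintf('"%s": [%s, %s, %s]', JOINT_NAMES,
                          fmt_num(j[, 1L]), fmt_num(j[, 2L]), fmt_num(j[, 3L])),
                  collapse = ", ")
    sprintf('{"t": %s, "joints": {%s}}', fmt_num(fr$t), body)
  }, character(1))
  out <- c(header, recs)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
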