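#' Define a pairwise joint-alignment rule
#'
#' A rule asserts that two named joints share, within an error range, the
#' same coordinate on one axis (x lateral or y vertical). Posture checks
#' are built entirely from such relative comparisons, which is what makes
#' monitoring independent of the patient's height.
#'
#' @param id Short unique rule name.
#' @param joint_a,joint_b The two joints compared; must differ.
#' @param axis `"x"` or `"y"`.
#' @param base_epsilon Error range in meters (> 0): the rule passes when
#'   the absolute coordinate difference is at most the effective epsilon.
#' @param body_part Label used for body-part masking, e.g. `"arms"`,
#'   `"trunk"`, `"legs"`, `"shoulders"`.
#' @return An object of class `alignment_rule`.
#' @export
alignment_rule <- function(id, joint_a, joint_b, axis, base_epsilon,
                           body_part) {
  joint_a <- match.arg(joint_a, JOINT_NAMES)
  joint_b <- match.arg(joint_b, JOINT_NAMES)
  axis <- match.arg(axis, c("x", "y"))
  if (identical(joint_a, joint_b)) stop("rule joints must differ")
  if (!is.numeric(base_epsilon) || base_epsilon <= 0) {
    stop("base_epsilon must be > 0")
  }
  structure(list(id = id, joint_a = joint_a, joint_b = joint_b, axis = axis,
                 base_epsilon = as.numeric(base_epsilon),
                 body_part = body_part),
            class = "alignment_rule")
}

#' Define a posture template
#'
#' A named set of alignment rules encoding one posture (e.g. standing
#' upright with arms at the sides).
#'
#' @param name Template name.
#' @param rules List of [alignment_rule] objects with unique ids.
#' @return An object of class `posture_template`.
#' @export
posture_template <- function(name, rules) {
  ids <- vapply(rules, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate rule id: ", ids[duplicated(ids)][1L])
  }
  structure(list(name = name, rules = rules), class = "posture_template")
}

#' @export
print.posture_template <- function(x, ...) {
  cat(sprintf("<posture_template> '%s', %d rules\n", x$name, length(x$rules)))
  for (r in x$rules) {
    cat(sprintf("  %-18s %s ~ %s on %s, eps %.3f m  [%s]\n", r$id,
                r$joint_a, r$joint_b, r$axis, r$base_epsilon, r$body_part))
  }
  invisible(x)
}

#' Therapist-tunable threshold configuration
#'
#' The tunable surface of the monitor: a global strictness multiplier on
#' all error ranges, absolute per-rule overrides, the set of body parts to
#' check, the lean threshold for the balance scale, and the debounce length
#' for fault events.
#'
#' @param strictness Positive multiplier applied to every rule's
#'   `base_epsilon` (smaller values = stricter monitoring).
#' @param overrides Named numeric vector/list mapping rule id to an
#'   absolute epsilon in meters; an override beats strictness scaling.
#' @param included_parts Character vector of body-part labels to check;
#'   must be non-empty.
#' @param balance_epsilon Dimensionless lean threshold: the balance scale
#'   alerts when the shoulder-width-normalized lean magnitude exceeds it.
#' @param debounce_frames Minimum consecutive violating frames before a
#'   fault event fires (integer >= 1).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(strictness = 1.0, overrides = list(),
                             included_parts = c("shoulders", "trunk",
                                                "arms", "legs"),
                             balance_epsilon = 0.1, debounce_frames = 5L) {
  if (!is.numeric(strictness) || strictness <= 0) {
    stop("strictness must be > 0")
  }
  overrides <- as.list(overrides)
  if (length(overrides) > 0L) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("overrides must be named by rule id")
    }
    if (any(unlist(overrides) <= 0)) stop("override epsilons must be > 0")
  }
  included_parts <- as.character(included_parts)
  if (length(included_parts) == 0L) {
    stop("included_parts must be non-empty")
  }
  if (!is.numeric(balance_epsilon) || balance_epsilon <= 0) {
    stop("balance_epsilon must be > 0")
  }
  debounce_frames <- as.integer(debounce_frames)
  if (is.na(debounce_frames) || debounce_frames < 1L) {
    stop("debounce_frames must be an integer >= 1")
  }
  structure(list(strictness = as.numeric(strictness), overrides = overrides,
                 included_parts = included_parts,
                 balance_epsilon = as.numeric(balance_epsilon),
                 debounce_frames = debounce_frames),
            class = "threshold_config")
}

#' Effective error range of a rule under a configuration
#'
#' A per-rule override is absolute and wins; otherwise the rule's base
#' error range is scaled by the global strictness multiplier.
#'
#' @param rule An [alignment_rule].
#' @param config A [threshold_config].
#' @return Effective epsilon in meters.
#' @export
effective_epsilon <- function(rule, config) {
  ov <- config$overrides[[rule$id]]
  if (!is.null(ov)) return(as.numeric(ov))
  rule$base_epsilon * config$strictness
}

#' Check one alignment rule on a frame
#'
#' Computes the signed coordinate difference `coord(joint_a) -
#' coord(joint_b)` on the rule's axis. The rule passes when the absolute
#' difference is zero or inside the effective error range (boundary
#' inclusive).
#'
#' @param frame A valid [skeleton_frame].
#' @param rule An [alignment_rule].
#' @param config A [threshold_config].
#' @return A `rule_verdict`: list with `id`, `difference` (m, signed),
#'   `effective_epsilon` (m) and `pass`.
#' @export
check_alignment <- function(frame, rule, config = threshold_config()) {
  eps <- effective_epsilon(rule, config)
  d <- frame$joints[rule$joint_a, rule$axis] -
    frame$joints[rule$joint_b, rule$axis]
  structure(list(id = rule$id, difference = unname(d),
                 effective_epsilon = eps, pass = abs(d) <= eps),
            class = "rule_verdict")
}

#' Evaluate a posture template on a frame
#'
#' Evaluates every rule whose body part is included in the configuration
#' and aggregates into an overall verdict. Joints of failing rules are
#' reported as misaligned so corrective feedback can name them.
#'
#' @param frame A valid [skeleton_frame].
#' @param template A [posture_template].
#' @param config A [threshold_config]; its `included_parts` selects which
#'   rules are checked.
#' @return A `posture_verdict`: list with `template`, `verdicts` (list of
#'   rule verdicts), `correct` and `misaligned_joints`.
#' @export
evaluate_posture <- function(frame, template, config = threshold_config()) {
  keep <- vapply(template$rules,
                 function(r) r$body_part %in% config$included_parts,
                 logical(1))
  rules <- template$rules[keep]
  if (length(rules) == 0L) {
    stop(sprintf("template '%s' has no rules in the included body parts (%s)",
                 template$name, paste(config$included_parts, collapse = ", ")))
  }
  verdicts <- lapply(rules, check_alignment, frame = frame, config = config)
  fails <- !vapply(verdicts, function(v) v$pass, logical(1))
  mis <- character()
  for (r in rules[fails]) mis <- c(mis, r$joint_a, r$joint_b)
  structure(list(template = template$name, verdicts = verdicts,
                 correct = !any(fails),
                 misaligned_joints = sort(unique(mis))),
            class = "posture_verdict")
}

#' Default upright posture template
#'
#' One rule per clause of the target standing posture: standing up with
#' the back straight, arms close to the body without lifting, and feet
#' aligned with the shoulders. Default error ranges are sized to typical
#' adult anthropometry and are fully overridable through
#' [threshold_config()].
#'
#' @return A [posture_template] named `"upright"`.
#' @export
upright_template <- function() {
  posture_template("upright", list(
    alignment_rule("shoulders_level", "ShoulderLeft", "ShoulderRight", "y",
                   0.04, "shoulders"),
    alignment_rule("hips_level", "HipLeft", "HipRight", "y", 0.04, "trunk"),
    alignment_rule("back_straight", "ShoulderCenter", "HipCenter", "x",
                   0.04, "trunk"),
    alignment_rule("hand_left_at_side", "HandLeft", "HipLeft", "x",
                   0.12, "arms"),
    alignment_rule("hand_right_at_side", "HandRight", "HipRight", "x",
                   0.12, "arms"),
    alignment_rule("hand_left_not_lifted", "HandLeft", "HipLeft", "y",
                   0.15, "arms"),
    alignment_rule("hand_right_not_lifted", "HandRight", "HipRight", "y",
                   0.15, "arms"),
    alignment_rule("foot_left_under_shoulder", "AnkleLeft", "ShoulderLeft",
                   "x", 0.10, "legs"),
    alignment_rule("foot_right_under_shoulder", "AnkleRight", "ShoulderRight",
                   "x", 0.10, "legs")
  ))
}

# rules compatible with gait: during the walking phase only trunk/shoulder
# symmetry is enforced (arm swing and stepping are part of walking)
WALKING_PARTS <- c("shoulders", "trunk")

#' Restrict a template to the rules meaningful during walking
#'
#' @param template A [posture_template].
#' @return The template keeping only shoulder/trunk rules.
#' @export
walking_template <- function(template) {
  keep <- vapply(template$rules, function(r) r$body_part %in% WALKING_PARTS,
                 logical(1))
  posture_template(paste0(template$name, "_walking"), template$rules[keep])
}

#' Remove body parts from a posture template
#'
#' Therapists can exclude body parts from checking (for example a patient
#' with restricted arm mobility); this drops every rule whose body part is
#' excluded. Excluding everything only errors later, when the emptied
#' template is evaluated.
#'
#' @param template A [posture_template].
#' @param excluded_parts Character vector of body-part labels to drop.
#' @return A [posture_template] without the excluded rules.
#' @export
mask_rules <- function(template, excluded_parts) {
  keep <- vapply(template$rules,
                 function(r) !(r$body_part %in% excluded_parts), logical(1))
  posture_template(template$name, template$rules[keep])
}

#' Lateral balance level from shoulder asymmetry
#'
#' The balance scale: signed lean, normalized by shoulder width so the
#' measure is height- and build-independent.
#' `value = (ShoulderLeft.y - ShoulderRight.y) / |ShoulderLeft.x -
#' ShoulderRight.x|`, clamped to \[-1, 1\]. A negative value means the left
#' shoulder is the lower one, i.e. the patient leans toward their left.
#' The alert fires when the magnitude exceeds the configured
#' `balance_epsilon` (boundary itself does not alert).
#'
#' @param frame A valid [skeleton_frame].
#' @param config A [threshold_config] (supplies `balance_epsilon`).
#' @return A `balance_level`: list with `value` in \[-1, 1\], `side`
#'   (`"left"`, `"right"` or `"none"` — the side of the lower shoulder),
#'   and `alert`.
#' @export
balance_level <- function(frame, config = threshold_config()) {
  dy <- frame$joints["ShoulderLeft", "y"] - frame$joints["ShoulderRight", "y"]
  width <- abs(frame$joints["ShoulderLeft", "x"] -
                 frame$joints["ShoulderRight", "x"])
  if (width < 1e-3) {
    stop("degenerate shoulder width (< 1 mm); cannot estimate lean")
  }
  value <- max(-1, min(1, unname(dy / width)))
  side <- if (abs(value) <= config$balance_epsilon) "none"
          else if (value < 0) "left" else "right"
  structure(list(value = value, side = side, alert = side != "none"),
            class = "balance_level")
}
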