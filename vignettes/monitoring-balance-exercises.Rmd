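---
title: "Monitoring balance-rehabilitation walking exercises from skeleton streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring balance-rehabilitation walking exercises from skeleton streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabwalk)
```

## The monitoring problem

People with balance disorders — typically after brain injury or with a
neurodegenerative condition — rehearse a simple but demanding exercise:
stand still in an upright posture, walk a straight 5 m course without
losing balance or drifting off the line, and stop at the finish line,
again holding the upright posture. Doing this at home requires an
automatic supervisor: something that watches the patient's posture
continuously, corrects them in the moment, and summarizes each attempt
for the physiotherapist who tunes the difficulty remotely.

`rehabwalk` implements that supervisor as a sensor-independent engine.
Its input is a stream of *skeleton frames*: time-stamped snapshots of 20
named body joints, each a 3-D position in meters (x lateral, y vertical,
z along the walking direction). Consumer depth sensors emit exactly this
representation; the package neither knows nor cares which device
produced it.

## Posture as pairwise joint alignment

The core idea is deliberately simple. A posture constraint is a
statement that two joints should share a coordinate on one axis — the
shoulders should be at the same height (y), an ankle should sit below
its shoulder (same x), the shoulder centre should be vertically above
the pelvis (same x). Each such *alignment rule* passes when

$$|c_a - c_b| \le \varepsilon,$$

where $c_a, c_b$ are the two joints' coordinates on the rule's axis and
$\varepsilon$ is the rule's *error range* in meters. The boundary is
inclusive: the difference must be *zero or inside* the error range.

Because every check is a coordinate *difference*, the verdicts are
invariant under whole-body translation, and a posture whose ideal
differences are zero stays correct under uniform scaling — this is
precisely why the method works regardless of the patient's height, and
both invariances are enforced by property tests against a brute-force
oracle.

The default `upright_template()` encodes the exercise posture with one
rule per clause: shoulders level (y, ε = 0.04 m), hips level (y,
0.04 m), back straight laterally (shoulder centre vs pelvis, x,
0.04 m), each hand at its hip laterally (x, 0.12 m) and not lifted (y,
0.15 m), and each ankle under its shoulder (x, 0.10 m). The posture
description names the constraints but no tolerances; these defaults are
sized to typical adult anthropometry and every one of them is
overridable. A forward-slump rule (shoulder centre vs pelvis on z) is
deliberately *not* in the default template — the framework restricts
itself to the vertical–horizontal (x/y) comparisons — but can be added
as an ordinary rule by any user who wants it.

### The therapist-tunable surface

`threshold_config()` collects everything a therapist adjusts as the
patient progresses:

* `strictness` — a positive multiplier on every rule's error range
  (smaller = stricter). Monitoring starts lax and tightens over weeks.
* `overrides` — absolute per-rule epsilons. An override beats
  strictness scaling, because a rule the therapist has set explicitly
  should not drift when the global knob moves.
* `included_parts` — the set of body parts actually checked (`arms`,
  `legs`, `trunk`, `shoulders`). A patient with restricted arm mobility
  can have the arm rules masked out entirely.
* `balance_epsilon` (default 0.1, dimensionless) and `debounce_frames`
  (default 5) — described below.

### Balance level

Lateral lean is estimated from shoulder asymmetry, normalized by
shoulder width so the measure is dimensionless and build-independent:

$$\mathrm{balance} = \frac{y_{\mathrm{ShoulderLeft}} - y_{\mathrm{ShoulderRight}}}
{|x_{\mathrm{ShoulderLeft}} - x_{\mathrm{ShoulderRight}}|} \in [-1, 1].$$

A negative value names the left side (left shoulder lower), positive
the right. When the magnitude exceeds `balance_epsilon` the balance
scale alerts and a corrective arrow points toward the *opposite* side —
the direction the patient must move to recover. A shoulder width under
1 mm is degenerate (a side-on or collapsed skeleton) and is an error
rather than a guess.

## The three-step state machine

An attempt is driven by a `step` variable that only ever increases:

1. **Start hold.** The pelvis must be within `start_zone_tolerance`
   (0.15 m) of the start line *and* the full upright template must pass.
   The hold clock accumulates over consecutive compliant frames and any
   non-compliant frame resets it to zero — the posture must be held
   *without swinging*. After `hold_seconds` (3 s) the walk begins.
2. **Walk.** Each frame is checked for balance (alert + corrective
   arrow), for the shoulder/trunk subset of the posture template
   (misaligned-bones feedback naming the offending joints), and against
   the corridor: the walking lines at `corridor_center_x ±
   corridor_half_width` (0.25 m), crossed when any of the two ankles or
   the pelvis passes a line (standing exactly on the line is not a
   touch). Arm and foot rules are deliberately excluded here — arm
   swing and stepping are part of gait, not faults. Pelvis advance
   drives the progress fraction, and crossing the finish line enters
   step 3.
3. **Finish hold.** Identical to step 1 at the finish line. On
   completion the attempt terminates with either a congratulation
   (error-free) or a conclusions list, one correction message per
   distinct fault observed, ordered by first occurrence.

The finish crossing is detected on the pelvis (`HipCenter.z ≥
finish_z`): the pelvis is the most stable tracked point and the same
joint that defines progress, so the course is measured consistently at
one body landmark. Backward courses are supported by mirroring the z
mapping; they reuse the identical machinery.

### Debouncing and error counting

Raw per-frame verdicts flicker. A fault therefore fires only after
`debounce_frames` consecutive violating frames, and one *maximal*
consecutive violating run counts as exactly one error, timestamped from
its first violating frame to its last. This matches how errors are
counted in the session report — as countable incidents, not frames —
and is verified property-style against an independent run-length-encoding
oracle on random violation masks.

Severity follows risk: margin touches and balance alerts are
*intrusive* (they relate to fall risk), task instructions and
misaligned-bones feedback are *informational*. Feedback payloads never
contain timing: attempt durations are recorded for the therapist but
deliberately hidden from the patient, so no event payload carries a
clock.

## The synthetic walker

`walking_stream()` generates the full exercise from an articulated
walker built on fixed anthropometric proportions (fractions of height;
shoulder width 0.259 H, pelvis height 0.53 H, shipped as a plain-text
table). Ankles are placed under the shoulders because that is the
stance the exercise demands. The walker stands at the start for the
hold time plus 0.5 s of slack, advances at constant speed (default
0.5 m/s — slow, impaired gait, covering 5 m in 10 s), and stands at the
finish. Controllable impairments:

* **Lean** is modeled as a vertical shear about the pelvis: every joint
  above the pelvis drops by its lateral lever arm times
  $\sin(\text{lean})$, with x unchanged. We chose the shear over a
  rigid rotation deliberately: it produces exactly the shoulder
  asymmetry the detector measures, so the balance level recovers
  $\sin(\text{lean})$ *exactly* (to 1e-9 in the noiseless tests), which
  makes the detector–simulator consistency a sharp-threshold property
  rather than an approximate one. For the small lean angles relevant
  here (under ~15°) shear and rotation differ by under 2% of the
  displacement.
* **Drift** adds a lateral offset proportional to advance
  (m per m), reproducing a walker veering off the line; the corridor
  crossing point is then analytically known and tested.
* **Sway** is a whole-body lateral sinusoid (default 2 cm at 0.6 Hz) —
  a translation, hence invisible to posture rules, visible to the
  corridor.
* **Noise** is iid Gaussian jitter per coordinate (default 3 mm,
  typical of consumer depth sensors), drawn in a fixed joint order from
  a single seeded generator so identical parameters and seed reproduce
  the stream bitwise after canonical serialization.

`inject_fault()` stamps a lean step-change, a drift offset, or a frame
freeze into a time window and records the ground truth, giving labeled
fixtures for every detector.

What the generator does *not* emulate: real gait dynamics (no inverse
kinematics, no ground contact, the legs translate rigidly), occlusion
and joint-tracking dropouts, and sensor-specific bias fields. Passing
tests therefore demonstrate the *monitoring logic* — thresholds, state
transitions, debouncing, reporting — under controlled kinematics, not
robustness to real capture artifacts. Incomplete frames are rejected at
parse time rather than imputed, because the monitor should not invent
joint positions for a safety-relevant check.

## Numerical and design choices

* Boundary convention: rule boundaries are inclusive (pass), the
  balance threshold is exclusive (|value| must *exceed* it to alert),
  and the corridor line itself is not a touch.
* Streams serialize with coordinates at nine decimal places; the
  round-trip guarantee is 1e-9 m, far below sensor noise.
* Timestamps are float seconds relative to stream start; the `fps` in
  the header is nominal. All hold/debounce logic uses the timestamps.
* The hold clock resets to zero on any non-compliant frame. The
  alternative (tolerating isolated bad frames) was rejected as it would
  silently relax the "without swinging movements" requirement; sensor
  flicker is instead absorbed by the error ranges themselves.
* Multi-attempt recordings are split where consecutive frame
  timestamps gap by more than `rest_gap` (default 5 s): in a home
  recording the capture pauses between attempts, so a time gap is the
  observable rest marker.
* Reports store totals alongside attempts and recompute them on load;
  a mismatch is an integrity error, so a tampered or truncated report
  cannot be read silently.
* Error ranges are absolute meters. A normalization hook exists in the
  sense that every epsilon is per-rule overridable; a fully normalized
  (per-height) rule system was left out because the pairwise-difference
  design already removes the dominant height dependence.

Default problem sizes used throughout the tests and the acceptance
script — a 5 m course at 0.5 m/s and 30 fps, i.e. roughly 500-frame
streams, 1000-frame random-verdict oracles, 300+ frames for noisy lean
recovery — were chosen as the smallest sizes at which every statistical
check is comfortably stable.

## A worked attempt

```{r}
spec <- exercise_spec()
stream <- walking_stream(walker_params(noise_sd = 0, seed = 1), spec)
res <- run_attempt(stream, spec)
res$result$success
res$state$transitions
```

Injecting a 10° lean between seconds 5 and 8 produces exactly one
balance error run covering the fault window:

```{r}
faulty <- inject_fault(stream, "lean", c(5, 8), magnitude = 10)
res2 <- run_attempt(faulty, spec)
res2$result$error_events[
  vapply(res2$result$error_events, `[[`, "", "id") == "balance"]
res2$result$conclusions
```

## Limitations

The engine monitors one exercise family (straight-course walking with
upright holds) with linear-threshold rules; it does not classify
arbitrary postures, estimate joint angles, or detect falls beyond
threshold alerts. The backward course direction is implemented as a
mirrored mapping but has no dedicated test fixtures. All quantitative
results in this vignette are computed by the package itself at build
time; no external measurements are reported.
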