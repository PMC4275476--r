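Package: rehabwalk
Title: Sensor-Independent Monitoring of Balance-Rehabilitation Walking Exercises
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Engine for monitoring a home balance-rehabilitation exercise from
    a stream of 20-joint skeleton frames. Posture is evaluated with pairwise
    joint coordinate-difference rules under therapist-tunable error ranges; a
    three-step state machine (start hold, 5 m straight walk, finish hold)
    drives corrective feedback events, debounced fault detection, lateral
    balance estimation from shoulder asymmetry, and per-attempt session
    statistics. Includes a seeded synthetic articulated walker with
    controllable lean, drift, sway and noise so the full pipeline is testable
    without capture hardware, plus a JSONL stream dialect and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
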