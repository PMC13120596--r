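Package: deskposture
Title: Desk-Based Dual Time-of-Flight Posture Monitoring and Criterion Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for monitoring occupational sedentary behavior with a
    dual time-of-flight distance sensor mounted at a desk. Implements the
    differential distance classifier that turns two-channel distance
    streams (torso and head, sampled at 3.3 Hz) into sit/stand/away
    posture states, the 60-second clinical bout filter with
    time-conserving merge semantics, and desk-squat repetition counting.
    Provides the full criterion-validation toolkit used to assess such
    sensors against ground-truth event logs: greedy nearest-neighbour
    event alignment, delta-tolerance sensitivity curves and minimum
    acceptable delay thresholds, duration error summaries (MAE, 95%
    confidence intervals, count bias, per-user stratification),
    one-vs-rest classification metrics, and Bland-Altman agreement with
    proportional-bias regression. A scripted-protocol simulator renders
    office-worker behavior (postural bouts, desk departures, rapid squat
    cycles) into realistic sensor streams with dropout spikes, postural
    sway and chair-occlusion artifacts, so the whole pipeline can be
    exercised end to end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
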