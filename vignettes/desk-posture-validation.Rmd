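---
title: "Desk-based ToF posture monitoring: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-based ToF posture monitoring: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deskposture)
```

## The sensing model

A desk-mounted unit carries two time-of-flight rangers: one aimed at
the seated torso, one just above seated head height. Each returns the
distance in mm to the nearest reflecting surface at 3.3 Hz (0.3 s per
sample) and saturates at 8191 mm when nothing reflects within range.
The differential distance classifier maps each two-channel sample to a
posture state in three steps:

1. **Smoothing.** A trailing arithmetic mean of ω = 8 samples per
   channel suppresses transient ranging spikes. The first ω − 1 samples
   use a partial, growing window so the smoothed stream stays
   index-aligned with the raw one; dropping them instead would
   desynchronise every downstream timestamp for no robustness gain.
2. **Range gating.** A channel "detects" a person when its smoothed
   distance lies in [300, 2000] mm, inclusive at both ends (the source
   description of the gate does not specify open or closed endpoints;
   closed is the less surprising reading).
3. **Decision tree.** Torso-only detection → `sit`; both → `stand`;
   neither → `away`. The fourth combination — head without torso — is
   geometrically implausible for a person at the desk, so it is treated
   as transient noise: the previous state is held (with a warning)
   rather than inventing a fourth state.

Smoothing precedes gating because the filter is meant to condition the
*distances*, not the booleans: a gated-then-voted design would have
different (worse) spike behaviour near the gate edges.

### Latency is emergent, and it has a floor

The classifier has no modelled delay; its ~2-s reaction time is purely
the trailing window. One consequence matters everywhere below: a
channel sitting at the 8191-mm idle code can only cross the 2000-mm
gate edge after roughly 7 of the 8 window slots hold fresh in-range
values, i.e. about 2.1 s, and no in-gate target value can make it
faster. Transitions *out* of the gate (distance rising toward the idle
code) cross in 1–3 samples. Detection latency is therefore
asymmetric: entering `stand` or `sit` from an idle channel is slow
(≈ 1.8–2.7 s), entering `away` is fast (≈ 0.3–1.2 s). All round-trip
tolerances in the tests (φ = 100% at δ = 3 s; duration MAE ≤ ω·0.3 s =
2.4 s) are corollaries of this arithmetic, not tuned numbers.

## Bouts, the clinical filter, and repetitions

Transition events (timestamp, new state) delimit bouts; bout *i* lasts
*D_i = t_{i+1} − t_i*, with the final bout closed at end of recording.
Activity bouts need about a minute to be cardiometabolically
meaningful, so stand/away bouts shorter than `min_bout` = 60 s are
treated as fragmentation noise. Crucially the filter *reassigns* that
time instead of deleting it: each internal sub-threshold stand/away
bout is appended to the immediately preceding retained bout (runs
accumulate into the same predecessor), a leading sub-threshold bout —
having no predecessor — merges forward, and the final bout survives
regardless because the recording may simply have been truncated.
Sitting is never filtered: the clinical question is whether *activity*
was sustained, and erasing short sits would overstate activity. Merges
that create equal-state neighbours coalesce. Two properties pin the
semantics down and are asserted on randomized bout sequences: exact
time conservation, and idempotence.

The canonical fragmentation scenario — a 90-s stand split 33 s / 1-s
sway blip / 56 s after a sway artifact, preceded by a 60-s sit — ends
as a 94-s sit plus the truncated trailing 56-s stand. The narrative
this scenario comes from totals 151 s out of a 150-s interval (a ~1-s
rounding slip in the prose); this package conserves time exactly, so
its tests assert the 94-s merge and exact conservation rather than the
printed trailing figure.

Desk-squat repetitions are counted on the **unfiltered** log (the 60-s
parameter gates interventions, not the classifier; a ~3-s squat
half-bout would otherwise be erased). A cycle is a full sit→stand→sit
excursion. The state before the first logged event is taken as seated
— the squat is prescribed from the working posture — so a log opening
with a stand event can complete its first cycle; an unterminated final
stand is reported as half a cycle, separately. Correctness is
ψ = 100 · detected/scripted.

## Temporal validation

Sensor and truth logs are aligned by a globally greedy rule: repeatedly
pair the unmatched (sensor, truth) events with smallest |Δt|, ties
broken toward the earlier truth event, then the earlier sensor event,
until one side is exhausted. The matching is deliberately state-blind:
temporal fidelity and label fidelity are different questions, answered
by different instruments (the sensitivity curve and the confusion
matrix respectively). No tolerance is applied during matching;
tolerances enter afterwards, so one alignment serves the whole δ grid.

* Sensitivity φ_δ = 100 · #(pairs with |Δt| ≤ δ) / |G|, non-decreasing
  in δ by construction.
* δ_min is the smallest grid tolerance not exceeding the hard cap
  δ_T = 5 s at which no grid tolerance up to δ_T improves φ by more
  than `plateau_epsilon` (default 0, a strict plateau; the parameter
  exists because empirical curves plateau asymptotically rather than
  saturate). If the curve is still rising at δ_T, δ_min falls back to
  δ_T with a warning: longer delays would help, but are operationally
  unacceptable for real-time prompting.
* Error metrics use only pairs with |Δt| ≤ δ_min. Each event is scored
  through the duration of the bout it opens: MAE in seconds (reported
  with the SD of absolute errors), mean signed difference in minutes
  with a normal-theory 1.96·σ/√n 95% CI (the printed convention for
  this statistic; not a t quantile), and count bias = raw sensor count
  − raw truth count, per state. A missed transition therefore shows up
  twice, coherently: −1 in count bias, and the preceding sensor bout
  lengthened by exactly the missed bout's duration.

**Greedy vs optimal.** On logs whose transitions are separated by tens
of seconds and whose latency jitter is a few seconds — the regime this
sensor produces — greedy matching coincides with exhaustive
minimum-total-cost matching, and a randomized oracle test asserts
exactly that (≤ 8 events per log, full enumeration). The equivalence
provably breaks when a missed truth event and a spurious sensor event
co-occur in one pair of logs: both matchings must then form one
"residual" far pairing, and a total-cost optimum can trade it against
cascades of slightly-worse good pairs. That residual pairing always
exceeds δ_T, so it is excluded from every reported statistic; the
oracle test accordingly draws clean, miss-only and spurious-only
instances.

## Classification metrics and agreement

Every ground-truth event contributes one cell of the 3×3 confusion
table: matched pairs contribute (truth state → sensor state); a missed
truth event is attributed to the sensor's *prevailing* state at that
time (what a reader of the sensor log would have believed), so row
sums always equal the scripted class totals. Spurious sensor events do
not enter the table — they are visible in the count bias. One-vs-rest
binarisation gives precision, recall, specificity and F1 per class; a
0/0 ratio is returned as `NaN` with an `undefined` flag, never as a
silent zero. Reported percentages are rounded to two decimals.

Bland–Altman agreement compares matched bout durations in minutes:
bias = mean(sensor − truth), 95% limits of agreement = bias ±
1.96·SD(d) with the n−1 SD (standard practice; the convention is not
stated in the source material). Proportional bias is the OLS slope of
differences on pair means — means rather than truth durations, the
conventional Bland–Altman regressor — with a two-sided t test;
degenerate inputs (constant differences or constant means, n < 3)
yield slope 0 and an undefined p rather than an error. The pair set is
all matches within δ_T, pooled across states, since agreement is a
property of the recording as a whole.

## The simulator: what it emulates and what it does not

`generate_script()` reproduces the three laboratory protocols: P1,
8 sit + 9 stand bouts per participant with durations uniform on
[60, 150] s; P2, 2 sit + 6 stand + 9 away bouts on the same range; P3,
10 squat cycles at 6 s per cycle as 20 alternating 3-s half-bouts
starting from the seated baseline. The per-participant counts are
chosen so a seven-participant panel yields exactly the published event
totals (56/63 in P1; 14/42/63 in P2; 140 squat transitions); the exact
per-session scripts were never published, so uniform durations on the
stated range are the neutral choice. Bout orders interleave the most
frequent remaining state first, which guarantees no two adjacent
equal-state bouts for the default counts.

`synthesize_stream()` maps states to target distances per participant:
seated torso interpolates 600→900 mm over heights 160→190 cm (taller
users sit further from a screen-mounted unit), standing torso and head
sit mid-gate (1150 mm; only gate membership matters), seated head is
the 8191-mm idle code. Artifact injections are all optional and
independently controlled: Gaussian ranging noise (15 mm SD, on
detecting samples only — the saturation code is a sentinel, not a
measurement), per-sample dropout spikes to the idle code (p = 0.005),
postural-sway excursions while standing (0.5–2 s, both channels out of
range — the mechanism that fragments standing bouts), and the
chair-occlusion effect (the chair back reading as a seated torso
during absence).

**Transition speed.** Scripted changes ramp the targets linearly over
`transition_ramp` = 0.3 s, one sampling interval. This models a
prompted postural change as sub-second movement, and it is also the
only regime in which the squat protocol is well-posed for temporal
matching: with stand-entry latency ≈ 2.4 s (the window-flush floor
above), a slower ramp pushes entry-plus-exit latency past the 3-s
half-cycle, at which point a sensor stand event lands nearer the
*next* scripted sit than its own cause and any state-blind
nearest-neighbour matcher must mispair. Relatedly, the squat cadence
itself has a detectability floor: a standing half-bout shorter than
about ω samples (2.4 s) can never pull the smoothed head channel into
the gate at all, so the scripted 3 s/half-cycle is close to the
fastest gesture this classifier can log.

What the simulator does **not** emulate: biomechanically realistic
kinematics (velocity profiles, overshoot), user deviation from the
script, clock drift between devices, multi-person desks, and the
hardware-specific idle-noise statistics of real arrays. Passing
round-trip tests on simulated streams therefore demonstrates internal
consistency of classifier + validation under controlled artifact
models — not field accuracy, which requires real participants.

## Problem sizes and determinism

The test suite and acceptance script run seven-participant panels per
protocol (≈ 6 000 samples per P1/P2 participant, 200 per P3
participant), randomized property tests with 10–40 replicates, and
exhaustive matching oracles up to 8 events per log — a few seconds in
total. Every stochastic step (script durations, panels, noise) is
driven by explicit seeds; per-participant RNG substreams derive from
one base seed, so any participant can be regenerated independently.
Timestamps are integer milliseconds throughout; durations are seconds
except Bland–Altman outputs in minutes, matching each statistic's
conventional unit.

## Known limitations

* The classifier cannot distinguish a static object at torso height
  from a person (the chair effect); the simulator reproduces the
  failure mode, and the mitigation (interactive per-desk calibration)
  is out of scope here.
* δ_min is grid-valued by definition; sub-second plateau onsets report
  as the next grid point.
* The greedy/optimal equivalence caveat above: with simultaneous
  misses and spurious detections the matching is greedy-defined, not
  total-cost-optimal, though never in a way that reaches any reported
  statistic.
* Per-user MAE uses the pooled sit-state δ_min for comparability
  across users; a per-user δ_min would conflate threshold selection
  with user variance.
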