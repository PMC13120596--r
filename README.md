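# deskposture

Privacy-preserving monitoring of occupational sedentary behaviour with a
desk-mounted, dual time-of-flight (ToF) distance sensor — and the full
criterion-validation toolkit needed to judge such a sensor against
ground truth.

A ToF ranger returns the distance (mm) to the nearest reflecting
surface and saturates at a maximum code (8191 mm) when nothing is in
range. Two of them at a workstation — one aimed at the seated torso,
one just above seated head height — are enough to distinguish three
postural states without a camera: only the torso in range means
**sit**, both in range means **stand**, neither means **away**. This
package is for digital-health and HCI researchers who want to (a) run
that classifier on recorded streams, (b) validate it event-by-event
against a reference measure, and (c) prototype the whole workflow with
no hardware at all via a scripted-behaviour simulator.

## What it computes

**Differential distance classifier** (`ddc()`): each channel is
smoothed with a trailing moving average of ω = 8 samples at 3.3 Hz,
gated on the detection range [300, 2000] mm, and passed through the
decision tree above. State changes are reduced to a transition log of
(timestamp, new state) events.

**Bouts and the clinical filter**: the duration of bout *i* is
*D\_i = t\_{i+1} − t\_i*. Stand/away bouts shorter than 60 s — the
minimum activity-bout duration considered cardiometabolically
meaningful — are not deleted but merged backward into the preceding
retained bout (`apply_clinical_filter()`), conserving total time
exactly. Desk-squat repetitions are counted as full sit→stand→sit
excursions on the *unfiltered* log, and correctness is
ψ = 100 · detected / scripted (`count_repetitions()`).

**Temporal validation**: sensor events S and ground-truth events G are
paired greedily by smallest |t − t′| (`align_events()`). Sensitivity at
tolerance δ is φ\_δ = 100 · #(pairs with |Δt| ≤ δ) / |G|; sweeping
δ = 1…10 s locates δ\_min, the smallest tolerance (≤ δ\_T = 5 s) where
the curve plateaus (`find_delta_min()`). Over matched events,
MAE = (1/n) Σ |S\_i − G\_i| on bout durations, the mean difference
carries a 1.96·σ/√n confidence interval, and count bias
= N\_sensor − N\_truth (`duration_errors()`, stratified per user by
`per_user_mae()`). One-vs-rest confusion matrices give per-class
precision, recall, specificity and F1 (`build_confusion()`,
`class_metrics()`), and Bland–Altman analysis gives mean bias, 95%
limits of agreement (bias ± 1.96·SD) and a proportional-bias slope
(`bland_altman()`).

**Simulator** (`simulate_participants()`): renders three scripted
office protocols — P1 sit/stand bouts of 60–150 s, P2 with desk
departures, P3 ten desk-squat cycles at 6 s per cycle — into
two-channel streams for participants of 160–190 cm, with Gaussian
ranging noise, dropout spikes, postural-sway artifacts and the
chair-occlusion effect available as controlled injections.

## Worked example

Simulate the sit/stand protocol for seven participants, classify every
stream, and validate against the scripted ground truth:

```r
library(deskposture)
study <- run_protocol_study("P1", n_participants = 7,
                            noise = noise_free(), seed = 11)
print(study)
```

```
Simulated protocol study: P1, 7 participants

Criterion-validation report
Event alignment
  119 sensor vs 119 truth events; 119 matched pairs
  0 missed truth, 0 spurious sensor events
  |delta| quartiles (s): 0 / 0.448 / 0.577 / 2.25 / 2.4
  sit  : sensitivity 100.0% at delta_min 1 s | MAE 1.80 s | count bias +0
  stand: sensitivity 100.0% at delta_min 3 s | MAE 1.71 s | count bias +0

Posture confusion matrix (truth rows x sensor columns)
       sensor
truth   sit stand away
  sit    56     0    0
  stand   0    63    0
  away    0     0    0
...
Bland-Altman agreement (minutes)
  n pairs    : 119
  mean bias  : 0.000 min
  95% LoA    : [-0.059, 0.059] (half-width 0.059)
```

Reading this: the seven scripted sessions contain 119 postural events
(56 sit, 63 stand); the classifier recovers every one (count bias 0)
within at most 2.4 s — the intrinsic latency of flushing an ω = 8
trailing window at 0.3 s per sample — so sensitivity is 100% inside a
3-s tolerance, duration errors stay below 2 s MAE, and the duration
agreement band is about ±3.5 s (±0.059 min).

The same pipeline runs from a shell via the thin wrapper in
`inst/cli/deskposture.R` (subcommands `simulate`, `classify`, `filter`,
`reps`, `validate`, `report`).

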