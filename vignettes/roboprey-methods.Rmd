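---
title: "Methods: arena simulation, multi-species tracking, and symbolic transfer entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arena simulation, multi-species tracking, and symbolic transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roboprey)
```

This vignette documents the models, estimators and numerical choices behind
the package, in the spirit of a methods section: what is computed, under
which assumptions, and where the genuinely open design decisions were made.

## The experimental setting

The package models a predator–prey ethorobotics assay: a mixed group of six
mosquitofish and six tadpoles swims in a white circular arena (42 cm
diameter, 10 cm water depth) observed from above at 20 frames/s. In the
robot-exposed treatment a biomimetic predator replica, driven by a planar
manipulator under the tank, patrols a stored trajectory and attacks the
mosquitofish that is currently closest to a tadpole, at approximately one
attack per minute. The scientific question downstream of the apparatus is
directional: does the fishes' behaviour drive the tadpoles' behaviour, or
vice versa, and how does the robot change that? The pipeline therefore ends
in a symbolic transfer-entropy analysis with a permutation test.

## Arena simulator

`simulate_trial()` integrates an agent-based model at the tracking clock
(`dt = 1/fps`, default 0.05 s). All lengths are in cm, times in s, angles
in radians.

**Mosquitofish** follow a correlated random walk with social forces: a
heading update combines cohesion toward the school centroid (weight 0.4),
alignment with the mean neighbour heading (0.3), close-range repulsion
inside 2.5 cm, wall avoidance inside a 3-cm margin, and predator avoidance
within a 10-cm perception radius; deterministic turning is capped at
6 rad/s and Gaussian heading noise (1.2 rad/√s at baseline) is added.
Cruising speed is 5 cm/s; fleeing fish gain an escape burst that fades
with sustained effort (escape bursts are anaerobic) and recovers away from
the predator. **Tadpoles** are slower (2.5 cm/s), non-schooling, avoid
collisions among themselves, and perceive the predator only within 3 cm —
they cannot visually detect it from afar. Animals cannot interpenetrate
each other (1-cm body exclusion) or sit under the solid robot body
(2.4-cm clearance, except the attacked fish, which is approached to the
1-cm standoff). The wall is reflective: a step that would exit the arena
is mirrored across the wall tangent and the heading updated accordingly,
so no positions are absorbed at the boundary.

**Behavioural state.** Each species carries a shared agitation process
(Ornstein–Uhlenbeck, 3-s correlation time, stationary SD 0.6) that
modulates turning noise and speed. Attacks kick the fish agitation upward
(impulse 2 × fear gain), producing the fear bursts the robot is designed
to elicit.

**Directed coupling** is the generator's ground truth for the inference
stage. Every half-second window the mean per-frame turning magnitude of
each species is summarised relative to its slow (30-s) running reference;
the other species' turning-noise multiplier holds that value constant over
the *next* window. The drive is therefore lagged by exactly one 0.5-s tick
— the same tick grid the transfer-entropy stage uses — with window
boundaries offset by two frames so that they align with the
displacement-based turning signal (which lags heading changes by two
frames). `coupling_spec()` defaults to (fear 1, fish→tadpole 0.5,
tadpole→fish 0): unidirectional coupling from fish to tadpoles. The gain
0.5 was fixed during generator design so that the coupled direction is
unambiguous (observed mean TE roughly an order of magnitude above the
plug-in bias floor) while the uncoupled reverse direction stays at its
nominal false-positive level; much larger gains make the tadpole series so
faithful a lagged copy of the fish series that, with single-symbol
histories, it begins to predict the fish series' own future beyond its
one-symbol past — a genuine (and well-known) short-history artefact of
symbolic transfer entropy, not a property of the estimator implementation.

**Robot controller.** Attacks are triggered by `schedule_attacks()`. The
tier is classified from the robot–target distance at trigger time:
contact (< 1 cm): turn toward the fish, hold 1 s, restore heading;
inspection (1–10 cm) and pursuit (> 10 cm): accelerate at 20 cm/s² (capped
at 20 cm/s) toward the live target position, stop at the 1-cm standoff,
hold 1 s, return to the pre-attack pose with the same speed profile, and
resume the patrol (the patrol clock pauses during attacks). Deceleration
into the standoff is trapezoidal at 20 cm/s², so commanded speed and
acceleration never exceed 20 cm/s and 20 cm/s² at any step; because the
live target moves, the final approach brakes to rest once inside a 1-cm
band around the standoff ("stopped at approximately 1 cm"), and a 6-s
pursuit cap bounds chases against persistently fleeing fish. Heading
changes (orienting toward the target, restoring the pose) are treated as
instantaneous, since no rotation-rate limit is part of the platform
contract. The patrol is a stored closed curve (a smoothed Lissajous figure
inside a 15-cm radius) resampled to constant arc length at 8 cm/s; any
stored curve satisfies the same contract.

**Attack scheduling.** Nominal rate is one attack per minute. Triggers are
generated sequentially: each gap is the nominal period plus a uniform 1–5 s
attack-time budget, and a trigger is kept only if its worst-case attack
(pursuit cap + hold + return across the arena, ≈ 10 s) completes within
the trial. Because every attack consumes at least one second beyond its
period, an hour-long trial always contains fewer than 60 attacks, matching
the operational behaviour of the platform; the expected count is 55–58.
(A simpler "uniform draw in each one-minute bin" scheme cannot guarantee
the strict sub-60 bound — the last bin's draw completes in time with
probability ≈ 0.9 — which is why the sequential scheme is used.)
Standardized trials draw exactly *n* triggers, one per equal-width bin
spanning the trial.

## Renderer and tracker

`render_frames()` rasterises agents as filled discs on a dark background
(gray 20) with additive Gaussian pixel noise: mosquitofish 60 px² at gray
170, tadpoles 240 px² at 110, robot 520 px² at 235, at 0.1 cm/px into a
480×480 image. Species are thus separable by area *and* intensity — the
body characteristics a real tracker uses — and the robot's distinct
intensity band is also what keeps its image from interfering with animal
detection. A configurable miss rate drops agents from frames to exercise
the gap-filling path.

`track_trial()` chains, per frame:

* **Multiple thresholding** — thresholds are fitted once from the pooled
  histogram of the first three frames (valleys between the background and
  blob intensity modes, via a smoothed density); each threshold level is
  labelled into connected components (EBImage), and components are merged
  across levels by centroid proximity, keeping each blob's representation
  at the *highest* threshold at which it appears, which separates touching
  animals of different brightness. Components outside all per-species area
  ranges are discarded as noise. Area bounds extend to roughly twice the
  single-animal area so that two merged same-species animals remain a
  (single) valid detection rather than vanishing.
* **Species classification** — a detection is labelled with the unique
  species whose area and intensity intervals both contain it; criteria
  must be pairwise disjoint on at least one feature. An optional motion
  context (typical species speeds) resolves detections whose features
  disagree.
* **Hungarian assignment** — detections are matched to the tracks'
  Kalman-predicted positions by minimising total Euclidean distance
  (`clue::solve_LSAP`), independently per species, with a 5-cm gate
  (far above any plausible per-frame displacement at 20 fps).
* **Constant-velocity Kalman filter** — state (x, y, vx, vy), white-
  acceleration process noise (q = 2 cm²/s³), measurement noise 0.01 cm².
  Matched tracks are updated; unmatched tracks are carried by the
  prediction and flagged `predicted`.

Occlusions get two specific treatments. A track whose prediction sits on a
same-species blob (two animals merged into one component) rides that
blob's centroid blended with its own prediction instead of extrapolating
blindly — identity is *not* resolved; swaps after occlusion are accepted,
because all downstream metrics are group-level and swap-tolerant. And in
this closed population (6 + 6 + 1, tracks seeded once), an unmatched
detection alongside an unmatched track means the track lost its animal
(e.g. filter divergence after a misassociation), so the track is re-seeded
on the detection. Pixel coordinates become arena-centred cm (y up) only at
the `track_set` boundary; all metrics operate in cm.

## Group-behaviour metrics

All metrics are computed frame-wise and then averaged over time (the only
reading that is well defined for moving animals): AFND averages each
individual's distance to its furthest group-mate over individuals and
frames; AIID averages all C(n,2) pairwise distances. Distance swam sums
successive displacements per individual (species value = mean over
individuals). Turning rate takes the unsigned angle between successive
displacement vectors over `dt`, skipping steps below a 0.1 cm motion floor
(heading is undefined at rest); displacement vectors rather than stored
headings make the metric applicable to tracker output. Region occupancy
assigns each sample to its half-open 3-cm ring `[3k, 3k+3)` (the outermost
ring includes the wall; a sample exactly at r = 15 cm falls in ring 5,
i.e. the external region, consistent with the central region being
r < 15 cm); central and external times partition the trial duration
exactly. Predicted (gap-filled) samples are included in all metrics, as in
the original real-time system, which had no means to exclude them.
`fulton_k()` implements the body-condition index K = weight/length³ × 10⁴
(g mm⁻³ 10⁴).

## Symbolic transfer entropy

`group_signal()` builds the two group-level signals on a 0.5-s tick grid:
the **turning magnitude** (mean over group members of |turning angle|/Δt,
averaged within each tick window — a rate is averaged) and the **central
count** (number of the species' individuals at radius < 15 cm, sampled at
the tick instant — a state is sampled). An hour-long trial yields 7,200
signal points and 7,199 symbols. `symbolize()` encodes increases as `+`
and ties or decreases as `-`.

`transfer_entropy()` is the plug-in estimator with single-step histories
on both sides: the joint mass over the eight (T(t+1), T(t), M(t)) triplets
is estimated by relative frequency, zero-probability terms contribute
nothing, and the result is in bits (non-negative by construction; the
implementation is checked against an independent exhaustive-enumeration
oracle over all pairs of length-8 binary sequences). Plug-in estimates on
finite series carry a positive bias of order (log₂e)/n bits; the
permutation test absorbs this bias because the null draws share it.

`permutation_test()` shuffles group identities across trials: the observed
statistic is the mean TE over trials with source and target from the same
trial; each of the `n_perm` permutations re-pairs every trial's target
series with the source series of a different, uniformly chosen trial, and
the result is significant when the observed mean exceeds the null's 95%
quantile (one-sided upper — the only direction in which "information
transfer" exceeds chance). The observed pairing never occurs among the
null draws. The per-pair TE values are precomputed once (an n×n matrix),
so the 20,000 permutations are lookups; reduced `n_perm` is used only in
calibration studies. Within a trial, gap-filled samples enter the signals
as-is; series of unequal length cannot be paired and raise an error.

## Problem sizes used in the automated checks

The packaged tests run the full chain at desk scale, chosen once as part
of the study design encoded here: tracker round trips use 10-s renderings
(200 frames); coupling recovery uses 20 replicates of 12 trials × 600 s
with 1,000 permutations; the null calibration uses 1,000 repetitions of 24
zero-coupling trials × 120 s with 500 permutations, where the measured
false-positive rate of the 95% rule sits near its nominal level
(≈ 0.06). The trial count matters here: because the observed pairing is
excluded from the null draws, the exceeds-the-95%-quantile rule is
intrinsically anticonservative when only a handful of trials is pooled —
a property of the rule itself, visible even with independent
identically-distributed TE values — and approaches the nominal 5% as
trials accumulate. The calibration therefore uses a trial count
representative of a pooled per-treatment analysis, which is where the
rule is used in practice.

## What the generator does and does not emulate

Passing tests on synthetic data show that the tracker and the inference
stage recover what the generator put in: species identities, positions to
sub-pixel accuracy, group statistics, and the direction of behavioural
coupling. The generator reproduces the geometry, clock, group sizes,
attack policy and kinematic envelope of the physical platform, and
realistic qualitative behaviour (schooling, wall-following, fear bursts).
It does not emulate video artefacts of a real rig (uneven illumination,
shadows, reflections at the wall, posture-dependent blob shape), sustained
multi-animal occlusions in three dimensions, or individual behavioural
heterogeneity; real-data performance of the detector and classifier
therefore cannot be inferred from these tests, while the assignment,
filtering, metric and information-theoretic layers are exercised exactly
as they would run on real trajectories.

## Known limitations

* Identity swaps after occlusion are uncorrected by design; per-individual
  analyses over long horizons would need a re-identification layer.
* Transfer entropy uses single-symbol histories, as in the printed
  estimator; with strong coupling the lagged-copy artefact described above
  is inherent to that choice.
* The turning-rate level of the simulated fish (≈ 4–6 rad/s) sits at the
  jittery end of the realistic range; it was chosen to give the symbolic
  signals enough variability at 0.5-s resolution.
* The patrol curve is a stand-in with the same contract as the platform's
  predator-inspired trajectory, which is not publicly specified.
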