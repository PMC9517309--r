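---
title: "Sit-to-stand kinematics and the seat comfort model: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sit-to-stand kinematics and the seat comfort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitstand)
```

## The problem and the data model

Rising from a seat is the principal mobility barrier and fall-risk activity
for healthy elderly users of living-room furniture. The pipeline analyzes
that transition from depth-sensor skeletal tracking: each frame is the 3D
position of 25 named joints in the camera frame (origin at the sensor,
x lateral, y up, z along the view direction, in meters), sampled at a fixed
interval. Frames with missing joints are rejected rather than imputed — the
downstream statistics (range extraction, clustering) are sensitive to
fabricated coordinates, and occlusion handling is out of scope.

Anthropometry is carried separately: standing measures L1–L14 and sitting
measures Z1–Z14, in millimeters (matching furniture dimensions), converted to
meters only where they parameterize the kinematic chain.

## The twelve joint angles

All angles are unsigned degrees in [0, 180], computed either as the
three-point angle at a vertex joint,
$\theta = \arccos\!\big(\vec{AB}\cdot\vec{AO} / (|\vec{AB}||\vec{AO}|)\big)$,
or as the angle between a body segment and a fixed reference direction,
optionally after projecting the segment onto the sagittal plane. The sagittal
plane is taken as the camera's y–z plane (x dropped), which assumes a subject
facing the sensor — a documented approximation, not a general-pose joint
coordinate system.

Two conventions required a decision, because the source descriptions of the
angle set conflict with the published per-angle ranges:

* **Trunk angle (`theta4`).** We measure neck→spine-base against gravity, so
  an upright trunk reads 0° and forward lean grows the angle. The published
  range tables use the opposite sense (≈180° upright). Both carry the same
  information; the synthetic keyframes therefore place their trunk targets at
  180° minus the published endpoints, which preserves the reported group
  difference (the elderly trunk range is much narrower than the control
  range). The definitions are data, not code: `default_angle_definitions()`
  returns a list the caller may override per angle id.
* **Elbow angle (`theta3`).** The prose describes a forearm-versus-gravity
  angle, but the published control range reaches 179.8° — full extension —
  which only the three-point shoulder–elbow–wrist angle attains. The
  three-point reading is the default.

The left limb takes suffix `_1`, the right `_2`. `mirror_frame()` (negate x,
swap left/right labels) exactly swaps the paired angle values — a property
test, since it exercises every definition at once.

## Seat geometry and the two thigh-angle conventions

With the knee as pivot and the thigh (length $x$) as radius, a seat surface
at height $y$ above the knee meets the thigh at
$\theta_5 = 90^\circ - \arctan(y/x)$, so $\theta_5 \in (0^\circ, 90^\circ]$
and `seat_height_for_angle()` is its exact inverse (round-trip tested to
1e-9°). The motion thresholds, however, measure the thigh against gravity:
90° seated-horizontal to 180° standing. The two conventions describe
different geometric constructions and cannot be merged into one identity;
the package bridges them with `seat_angle_band()`, which maps a
gravity-convention range to the seat-surface convention by
$\theta_{\text{seat}} = \theta_{\text{motion}} - 90^\circ$ (the thigh's
elevation above horizontal), clipped to (0°, 90°]. Under this bridge the
published right-thigh ranges imply a *higher* minimum recommended seat
height for the elderly band than for the control band, the direction of the
study-level conclusion; the alternative mapping ($180^\circ - \theta$)
reverses that direction and is not used.

## The synthetic motion generator

The generator exists because the study cohorts (≈4000 frames per group) are
not distributed. It emulates exactly the features the analysis consumes and
no more:

* a **planar (sagittal) kinematic chain** — ankle→knee→hip→spine→neck→head
  plus both arms — with segment lengths from the subject's anthropometry
  (shank L5; thigh Z9 − Z7; trunk 0.95·Z2; head 0.6·(Z1 − Z2); arms L2, L3)
  and paired joints at fixed lateral offsets;
* **four stage keyframes** (pre-rise, hip-raise, mid-rise, upright; 3 s
  each by default, ~12 s per transition) holding target angles, with cosine
  easing between stages. Ten angles are free chain parameters; the thigh
  elevations `theta5_*` follow from `theta6_*` and `theta7_*` (with a
  vertical shin, θ5 = θ6 — consistent with the published tables, where the
  elderly right-side θ5 and θ6 lower bounds coincide). Keyframes carrying an
  inconsistent θ5 target are rejected at validation;
* **additive Gaussian coordinate noise**, default 5 mm per coordinate,
  independent across joints and frames, seeded;
* default keyframe targets placed **inside the published per-cohort ranges**
  for each angle. They are fixture parameters, not estimates of the real
  cohorts. The default control upright knee/shin targets (θ6 = 177–178°,
  θ7 = 90–92.5°) stay clear of θ6 + θ7 > 270°, where the thigh would cross
  vertical during interpolation and the hip would momentarily descend;
* the default sampling interval is 1 s (the capture rate the pipeline
  assumes); the quick-start configuration uses 0.25 s so that a 12 s
  transition yields enough frames per stage to cluster.

Noise-free simulation satisfies three exact invariants used as oracles:
segment lengths are constant to 1e-9 m, the hip height is non-decreasing
from the hip-raise stage onward, and extracted thresholds equal the analytic
extremes of the eased keyframe interpolation at the sampled times.

What passing tests on this generator does **not** show: robustness to real
tracker artifacts (jitter spikes, swapped limbs, occlusion), to subjects not
facing the sensor, or to out-of-plane motion. The generator is planar and
smooth by construction; conclusions about real recordings require real
recordings.

## Clustering and stage structure

`cluster_postures()` runs k-means on the 12-dimensional angle vectors:
k-means++ seeding, 10 restarts, Lloyd iterations to a 1e-6 centroid-shift
tolerance, best restart by total within-cluster sum of squares. Seeding
samples rows in a canonical lexicographic order, so results are invariant to
frame order under a fixed seed. If a cluster empties (possible on degenerate
inputs), it is re-seeded at the point farthest from its assigned centroid.
The default granularity is fine k = 9 postures agglomerated to 4 coarse
stages by average-linkage clustering of the centroids (3 coarse phases are
one configuration away), since the transition is described at both
granularities. `stage_report()` orders stages by mean timestamp.

## Importance ranking

The stage label of each frame is predicted from the 12 angles with a
single-hidden-layer perceptron: 4 hidden units, covariates z-scored on the
training split (default 0.75), softmax output, fit via `nnet` (its logistic
hidden units span the same function class as tanh units, since
$\tanh(x) = 2\sigma(2x) - 1$; weight decay 1e-4 stabilizes the fit).
Importance is **permutation importance on the held-out split**: the mean
decrease in test accuracy over 20 independent permutations of each angle
column, clipped at zero, normalized to sum to one; the normalized importance
divides by the maximum so the dominant angle reads 100%. This choice follows
the normalization evident in the published table, whose importance column
sums to exactly 1.000. Test-split scoring (rather than training-split) is a
documented choice; the result object carries the raw accuracy drops and
their permutation standard errors so a near-null angle can be recognized
(drop within ~2 standard errors of zero). If no permutation reduces
accuracy, importances fall back to uniform with a flag rather than dividing
by zero.

A parameter-recovery property backs the procedure: across 100 seeded
replicates with labels generated from one angle only, that angle ranks first
in at least 95.

## AHP weighting

Criterion weights come from the principal eigenvector of the pairwise
judgment matrix (power iteration, 1e-12 tolerance), λ_max from the Rayleigh
quotient, CI = (λ_max − n)/(n − 1), CR = CI/RI(n) with the tabulated random
indices (orders 3–30 as published; orders 1–2 are 0 by convention), and
consistency iff CR < 0.1. Because the raw 30-expert matrix is not available,
the package also reproduces the published weighting directly from the
printed feature vector (`weights_from_feature_vector()`). Two printed values
of λ_max circulate (4.076 in prose, 4.067 in the table); only 4.067 is
arithmetically consistent with the printed CI of 0.022, so the table value
is used. CI/CR and percentage weights round to three decimals at
presentation, matching the published table.

## Comfort model

`default_mapping()` carries the ten published furniture elements (backrest
E1–E3, armrest F1–F2, seat surface G1–G4, legs H1) with their body values
and angle links verbatim — including the seat-width→right-elbow link (G1),
which has no geometric motivation; G1 is therefore *rated* by the
dimensional rule below, like the elements published without an angle.

`evaluate_seat()` computes an induced angle per mapped element (documented
proxies: backrest inclination → neck angle; backrest height shortfall below
the sitting shoulder height adds proportional trunk slump; armrest spacing
scales a right-angle elbow by spacing/Z13; seat height and inclination →
thigh-to-seat angle via the seat geometry with y = seat height − Z7; chair
leg height → seated knee angle 90° + atan((legs − Z7)/x)) and rates it
against the user's threshold range: **5 inside the range, minus one point
per started 25% of the range width outside, floored at 1**. The 1–5 scale is
published; this scoring function is the package's own construction (the
source defines no formula), chosen to be monotone — moving an induced angle
toward the range midpoint never lowers its rating, a property test.
Dimension-only elements rate 5 within ±10% of the mapped body value, minus
one point per further 10% of deviation.

`recommend_seat_height()` inverts the seat geometry over a comfort band:
heights `[x·tan(90° − θ_upper), x·tan(90° − θ_lower)]`, relative to the knee
pivot (add Z7 for a floor-relative height). The thigh length defaults to
Z9 − Z7, since no single published measure is designated as "actual thigh
length".

## Numerical choices and degenerate inputs

* Angle computations clamp the cosine into [−1, 1] before `acos`; zero-length
  vectors (coincident joints, or segments collapsing under sagittal
  projection) raise a degenerate-geometry error naming the angle and joints.
  Range extraction skips such frames with a count, erroring only if a whole
  sequence is degenerate.
* Motion CSVs are written with six decimals — lossless at 1e-6 m and
  byte-stable across writes; the column schema is fixed and published
  (`motion_schema()`).
* k-means ties in assignment break to the lowest centroid index; restart ties
  keep the first best.
* All randomness is routed through explicit integer seeds (cohort seeds spawn
  per-subject seeds; the pipeline config derives one child seed per stage
  from its master seed), never the wall clock.

## Problem sizes

The bundled quick-start runs 6 subjects per cohort at a 0.25 s interval
(~600 frames per cohort), clusters k = 9 → 4, and trains the perceptron once
— a few seconds end to end. The property suites use 100–250 observation
fixtures and 100 replicates for the recovery check; these sizes were chosen
so the full test suite completes in well under a minute while keeping the
statistical checks meaningful.

## Known limitations

* The planar chain cannot express abduction, axial rotation, or asymmetric
  stance width; left/right asymmetry enters only through per-side angle
  targets.
* Published threshold tables are carried as reference constants
  (`reference_thresholds()`); they are not recomputable because the
  underlying recordings are not distributed, and the synthetic thresholds
  are not expected to match them numerically — only directionally (e.g. the
  narrower elderly trunk range).
* The comfort scoring function and the induced-angle proxies are reasoned
  constructions, not validated instruments; ratings should be read as
  ordinal screening, not calibrated comfort.
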