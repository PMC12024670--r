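---
title: "Methods: RULA scoring, two acquisition branches, and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RULA scoring, two acquisition branches, and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulagree)
```

## The scoring model

RULA reduces a working posture to a 1–7 musculoskeletal-risk score in
three stages. First, each body region is banded into a sub-score from its
joint angle and modifier flags. `rulagree` uses the published worksheet
bands, with every boundary value assigned to the lower-scoring band
(`<=` comparisons throughout):

| region | bands (degrees) | modifiers |
|---|---|---|
| upper arm (1–6) | ±20 → 1; extension < −20 or 20–45 → 2; 45–90 → 3; > 90 → 4 | +1 shoulder raised, +1 abducted, −1 supported (floored at 1) |
| lower arm (1–3) | 60–100 → 1; outside → 2 | +1 across midline / out to side |
| wrist (1–4) | neutral → 1; ±15 → 2; beyond → 3 | +1 bent from midline |
| wrist twist (1–2) | mid-range → 1; near end range → 2 | — |
| neck (1–6) | 0–10 → 1; 10–20 → 2; > 20 → 3; any extension → 4 | +1 twist, +1 side tilt |
| trunk (1–6) | seated upright (±2) → 1; ≤ 20 → 2; 20–60 → 3; > 60 → 4 | +1 twist, +1 side tilt |
| legs (1–2) | supported → 1; not → 2 | — |

Second, table A maps (upper arm, lower arm, wrist, wrist twist) to
posture score A and table B maps (neck, trunk, legs) to posture score B;
the muscle-use and force/load increments are added to give scores A and
B. Third, table C maps (A, B) to the grand score, with inputs above its
last row/column clamped to the published "8+" row and "7+" column, so
every valid posture lands in 1–7. The tables are transcribed from the
standard worksheet; the original 1993 tables are assumed (no later
revision is modelled). The whole chain is deterministic and is verified
cell-for-cell against a second, independently transcribed copy of the
worksheet in the test suite.

Two modelling choices deserve a note. The worksheet does not state what
happens when the supported-arm "−1" would push the upper-arm score below
its scale, so the score floors at 1. And the increments (`muscle_use_*`,
`force_load_*`) are *fields with defaults*, not constants: static seated
assistance work fixes them at +1/+1 and 0/0 (held postures, no loads
over 2 kg), but the engine generalises to other protocols by setting
them per posture.

## Degenerate-input and tolerance choices

* **Trunk "seated, well supported".** A geometric trunk angle is never
  exactly 0°, so flexions within ±2° (configurable,
  `trunk_neutral_tol`) count as upright. 2° is well below the ~8° a
  band-2 trunk typically shows and above any numerical noise.
* **Wrist "neutral".** The neutral wrist band is a single position on
  the worksheet; a tolerance of 1e-9° keeps geometrically measured
  zeros in it without ever affecting a real (noisy) measurement.
* **Angles** must be finite; `NaN`/`Inf` raise a typed input error
  rather than propagating through the lookup tables.
* **Table C clamping** makes `grand_score()` total for all score pairs
  ≥ 1, so no posture can escape the 1–7 scale.

## The pose branch

The pose branch consumes two 17-keypoint snapshots (frontal and sagittal
camera views) plus a manual annotation file. Angle rules:

* upper arm — sagittal angle between the shoulder–hip line and the
  shoulder–elbow axis (signed; extension negative);
* lower arm — sagittal shoulder–elbow vs elbow–wrist;
* neck — sagittal shoulder–hip line (extended upward) vs shoulder–ear
  axis;
* trunk — sagittal hip→shoulder line vs the image vertical. The cameras
  are assumed levelled at a standardized height and distance, so the
  image vertical is treated as gravity-aligned;
* wrist — sagittal elbow–wrist line vs the *annotated* hand direction.
  No keypoint marks the hand, so hand alignment comes from the assessor;
  without it the wrist is declared unmeasurable (an explicit error)
  unless the configuration allows annotation-only wrist flags;
* abduction — frontal hip–shoulder vs shoulder–elbow angle over a 20°
  threshold; shoulder raised — frontal shoulder-line inclination over
  5°; neck side tilt — frontal eye-line inclination over a 3°
  tolerance; trunk side tilt — frontal hip-midpoint→shoulder-midpoint
  inclination over 10°; arm across the midline — the scored wrist's
  frontal x crossing the vertical through the hip midpoint.

The thresholds are configuration fields (`pose_config()`) because no
published values exist for them; the defaults are what a practitioner
would call a visible deviation. The eye-line tolerance is the largest
because the two eye keypoints are the closest landmark pair — at a
rendering scale of 6 px/cm they sit ~38 px apart, so even 2 px of
keypoint noise moves their line by several degrees. Transverse-plane
items (neck/trunk twist, forearm rotation, wrist midline bend, arm
support) cannot be seen by either a single-plane camera or the geometric
rules, and are always taken from the annotations.

All geometry is computed from normalised direction vectors, making every
extracted angle and flag invariant to uniform scaling and translation of
the keypoints (tested property). Keypoints below the confidence
threshold (default 0.3) are treated as occluded: if a rule needs them,
extraction stops with an error naming the keypoint — never a silent
default. Only one body side is scored (default right), matching
single-sided assessment protocols; the facing direction of the sagittal
camera is a configuration field. Displayed angles are not rounded before
banding.

## The IMU branch

A fixed-rate stream of complete posture inputs is scored frame by frame
and summarised by the **relative time spent in each grand-score level**.
The reduction to a single number is the time-weighted mean
$\sum_k k \cdot \text{fraction}(k)$, which is algebraically the
arithmetic mean of the per-frame grand scores (asserted to 1e-12 in the
tests); region scores are per-frame sub-score means. Continuous values
such as 4.82 are therefore the natural output. The full level
distribution is also returned so other reductions (mode, maximum,
fraction of time at level ≥ 5) remain available. No resampling,
filtering or windowing is applied to the stream.

## Agreement statistics

`rula_agreement()` compares paired per-participant scores from the two
branches, for the overall score and each region family:

* **Weighted kappa** on scores rounded half-up to integer levels
  (continuous aggregates have no canonical discretisation; half-up
  rounding to the region's own scale — 7 levels overall, 6/3/4/6/6 for
  the regions — is the least surprising). Weights are linear by default
  ($w_{ij} = 1 - |i-j|/(k-1)$), quadratic on request; both schemes are
  tested against a brute-force double-sum oracle. The CI uses the
  Fleiss–Cohen–Everitt asymptotic variance, the p-value the
  corresponding null variance. Degenerate marginals (chance agreement
  = 1) raise a typed error instead of returning 0/0.
* **Bland–Altman**: mean difference, sample SD (n−1) of the
  differences, limits mean ± 1.96 SD, with per-pair points for
  plotting.
* **Mann–Whitney U** with midrank ties, tie-corrected normal p-value
  without continuity correction (comparable to mainstream statistics
  packages); an exact path exists for tie-free data with
  $n_1 n_2 \le 400$. The rank-biserial correlation is
  $2U/(n_1 n_2) - 1$ with $U$ counting pairs where the first sample
  exceeds the second, so +1 means complete separation in favour of the
  first method.
* **Bonferroni** with family size defaulting to the number of score
  families tested (six: overall plus five regions), configurable.
* **Post hoc power** of the two-tailed point-biserial correlation
  t-test: noncentrality $\delta = r\sqrt{n}/\sqrt{1-r^2}$, df = n − 2.
  At r = 0.45, α = 0.05, n = 45 this computes to 91.05%, and a
  Monte-Carlo two-group simulation reproduces it within half a
  percentage point (tested). A Fisher-z bivariate-normal approximation
  is offered as a more conservative alternative (≈ 0.88 under the same
  configuration); the noncentral-t model is the default because it is
  the exact sampling model for a correlation t-test.

## What the synthetic cohort emulates

`cohort_config()` describes a cohort of seated static work postures:

* **Truth**: per-participant angles from truncated normals and flags
  from Bernoulli draws. The default means/SDs (upper arm 52 ± 20°,
  lower arm 80 ± 24°, wrist 13 ± 8°, neck 15 ± 11°, trunk 5 ± 4.5°,
  with flag prevalences between 0.08 and 0.45) describe moderate-risk
  seated assistance work; they were fixed once so that the noise-free
  cohort grand mean sits near 4.9, the middle of the moderate-risk
  band, with region means in the ranges this literature reports. The
  anthropometry defaults (stature 165 cm, shoulder height 138.74 cm,
  shoulder width 37.97 cm) are the cohort means of a seated
  dental-assistance study population, resampled per participant within
  the observed min/max.
* **IMU observation**: true angle + stationary AR(1) jitter (marginal
  SD 2°, lag-one coefficient 0.95 at 60 Hz) + linear drift
  (0.05°/s over a 30 s window). The marginal SD matches reported
  IMU joint-angle RMSEs (< 2.4°); the AR structure reflects that
  sensor error is slowly varying, and the drift term mimics heading
  drift. Flags are held at truth — IMU protocols fix them per capture.
* **Pose observation**: true angle + per-region bias + white angle
  error (default SD 5°, inside the 2–12° RMSE range reported for
  2D pose models), rendered into stick-figure keypoints at 6 px/cm
  and then jittered per keypoint (default 2 px). The default trunk
  bias is +8°: snapshot-based scoring tends to read the seated trunk
  as more flexed than the sensor stream does. Bias values are
  documented defaults, not claims.
* **Calibration**: `calibrate_pose_noise()` scales the two pose-noise
  components jointly by bisection until the Monte-Carlo expected
  overall kappa matches a target; expected kappa decreases
  monotonically in the noise scale (tested), which makes the search
  well posed. The packaged `"kappa_moderate"` preset (angle SD 4.75°,
  jitter 1.9 px) is the stored result of calibrating to κ = 0.45, the
  moderate-agreement regime reported when these two technologies are
  compared in the field.

What the generator does **not** emulate: multi-person scenes and
patient/assistant confusion, genuine occlusion patterns (confidences are
fixed, not pose-dependent), parallax and perspective distortion (the
projection is orthographic), magnetic disturbance events, left-handed
protocol variants, and assessor error in the transverse-plane
annotations (annotations are taken as read). Passing tests therefore
show that the pipeline is internally consistent and that its statistics
behave as designed under a plausible noise model — not that either
technology achieves any particular accuracy on real recordings.

A structural observation the simulator makes visible: under angle noise,
snapshot scoring is biased upward relative to the time-averaged stream
(about +0.4 grand-score points at the default noise), because the
banded score is a convex, step-wise function of angle near the common
working postures — noise can only push a mid-band posture into a higher
band. This asymmetry is a property of single-snapshot RULA, and it is
reported, not corrected.

## Problem sizes and numerical budgets

The test suite checks the lookup tables exhaustively (288 + 72 + 56
cells), the sub-score bands on a 0.25°-grid, geometry round-trips on
1000 random postures (recovery to 1e-6°), the kappa implementation
against a brute-force double sum on 500 random tables (1e-10), LoA
coverage on 10⁵ normal differences (±1%), and kappa recovery over 200
replicate cohorts of n = 45 (mean within ±0.05 of the 0.45 target).
Cohort simulations run at 60 Hz × 30 s; file-based pipeline tests use
shorter streams (10–20 Hz, 3–5 s) since stream length only changes the
averaging, not the code paths. All stochastic tests run under fixed
seeds.

## Known limitations

* The trunk tilt/twist items are defined subjectively in observational
  practice; the geometric trunk rules here are one defensible reading
  and are flagged as configuration, not ground truth.
* The asymptotic kappa CI is unreliable for very small n or extreme
  marginals; the degenerate case errors out, but near-degenerate tables
  will produce wide, approximate intervals.
* The exact Mann–Whitney path requires tie-free data; ordinal RULA
  scores are tie-heavy, so the tie-corrected normal approximation is
  the effective method at realistic sizes.
* Scores A and B accept arbitrary non-negative increments, but table C
  is only published up to "8+"/"7+"; unusual increment schemes saturate
  rather than extrapolate.
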