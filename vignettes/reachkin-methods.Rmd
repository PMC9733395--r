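---
title: "Models and methods behind reachkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reachkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachkin)
```

`reachkin` analyses 3D reaching movements recorded under three
visualization technologies (immersive VR, AR, 2D screen) in a
fruit-reaching paradigm: a cursor sphere is moved from a home sphere to a
target fruit, the target is "touched" when the cursor overlaps its
collider, and the participant returns home. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Task protocol and geometry

`build_protocol()` encodes both experiment variants: a 0.3588 × 0.2847 ×
0.3726 m workspace, eight blocks of 6/12/12/12/18/18/18/6 fruits (102
total) for the healthy-participant protocol, six blocks of 6/6/6/12/12/6
(48 total) for the patient protocol, a 0.4–0.6 s dwell interval at the
home sphere, a 4 cm cursor sphere, a 4 cm (or 5 cm, patient protocol) home
sphere, and per-fruit colliders (10 cm and 7.52 cm spheres for orange and
apple; a 5.78 cm sphere plus a 7.31 × 2.38 cm capsule for the pear). The
axis convention is right-handed: x = horizontal (right), y = vertical
(up), z = depth (away from the participant), matching screen coordinates
for the first two axes.

Targets are classified by **depth usage**: `no_depth` when the offset from
the workspace centre has no depth component beyond a tolerance,
`only_depth` when only the depth component exceeds it, `combined_depth`
otherwise. The tolerance defaults to 1 mm; generated locations carry exact
zeros on unused axes, so any small tolerance gives the same classes.

The exact coordinates of the 22 target locations are not part of the
published protocol — only their class structure is (8 no-depth: 2
horizontal, 2 vertical, 4 horizontal+vertical; 2 only-depth, one nearer
and one farther; 12 combined: 8 three-axis, 4 depth+horizontal).
`generate_location_set()` therefore places targets at grid-aligned
fractions (±1/3, ±2/3 of the half-extents) satisfying that structure, with
a small seeded jitter (±1/12 of the half-extent) on the axes each class
uses. The canonical set is fixed per seed and shared across participants
and conditions; whether the original locations were participant-specific
is unknown, and a shared set is the simplest assumption consistent with a
"pre-randomized" design.

Fruit categories are assigned per block under the protocol constraints
(pear-only first/last blocks; constrained category sets in between), and
locations are drawn uniformly avoiding immediate repeats.

## The synthetic-data generator

The generator exists so that segmentation, metrics, scoring and statistics
are testable end to end without human recordings. It is **not** a
biomechanical model; it produces data with the statistical structure the
analysis assumes.

Each trial is built from the minimum-jerk position profile
$s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5$, the standard model of smooth
point-to-point reaching: straight path, single symmetric speed peak of
$1.875\,D/T$. On top of it:

- **Latency phase** — the hand rests at the home position for a
  truncated-normal reaction latency (condition parameter; defaults
  0.30/0.34/0.40 s for IVR/AR/Screen).
- **Duration** — reach time is `baseline (3 s/m) × subject effect
  (log-normal, SD 0.15) × condition scale (1 / 1.08 / 1.18) ×
  subject-by-condition multiplier (log-normal, SD 0.05) × trial noise
  (log-normal, SD 0.08) × distance`. The subject-by-condition term is the
  within-subject error of the repeated-measures design.
- **Curvature** — a half-sine lateral bump perpendicular to the chord
  (peak 10/16/24 mm by condition) bends the path without moving the
  endpoints, raising the straightness ratio.
- **Corrective submovements** — a Poisson number (mean 0.4/0.7/1.1) of
  sequential minimum-jerk corrections: the main movement is rescaled to
  stop `k × 15 mm` short of the target and each correction covers 15 mm
  along the chord as its own minimum-jerk step after a brief pause. This
  is the classical sequential-submovement decomposition of corrected
  reaching; each correction contributes one isolated bell to the speed
  profile, so a reach with *k* corrections shows exactly `1 + k` velocity
  peaks. (A net-zero-displacement perturbation cannot do this: any
  out-and-back bump adds *two* speed extrema.)
- **Sampling** — a nominal 2 ms grid with clamped Gaussian timestamp
  jitter (SD 0.1 ms), forcing downstream resampling, plus isotropic
  Gaussian position noise (SD 1 mm, a typical consumer-tracker scale).
- **Contact** — the reach aims a few millimetres inside the
  cursor-plus-collider contact radius, so the final sample always
  satisfies `detect_collision()`; the collision time is the last reach
  sample. Return-to-home movements are generated and flagged so that
  segmentation demonstrably excludes them.

The effect magnitudes reproduce the expected ordering (screen reaches
slower, more curved, less smooth, later onsets than HMD reaches); they are
configuration, not empirical claims, and `null_effect_config()` makes all
conditions exchangeable for calibration studies.

`simulate_metric_table()` is a distribution-level fast path: it draws
per-trial metric values from the same generative parameters using the
closed forms (normalized duration includes the latency and the 0.38 s per
correction, peak speed is $1.875/\text{normalized duration}$, onset is the
latency plus the analytic 0.2 m/s threshold crossing, solved from
$\tau(1-\tau) = \sqrt{0.2\,T/(30 D)}$). Power and type-I calibration need
thousands of replicate datasets, which trajectory synthesis cannot supply
at any reasonable cost; a dedicated test verifies that fast-path cell
means agree with the trajectory pipeline on a shared seed.

What the generator does **not** emulate: biomechanics (joint limits, arm
dynamics, weight support), tracker dropout and latency, anticipatory or
premature movements, category-confusion counting errors, and the surplus
movements real sessions contain (restarts and repeated touches); with 17
subjects and the 102-fruit protocol it produces exactly 17 × 3 × 102
segments. Passing tests therefore validate the *pipeline*, not any claim
about human movement.

## Kinematic processing

Recordings are only approximately 500 Hz, so every segment is first
resampled to a uniform grid (linear interpolation), then low-pass filtered
with a zero-phase Butterworth filter (order-2 run forward and backward —
4th-order effective response — 10 Hz cutoff), and differentiated with
central differences; speed is the Euclidean norm of the filtered velocity.
Positions are filtered *before* differentiation: filtering the rectified
speed of raw 500 Hz positions would leave a large positive noise floor
(millimetre noise differentiates to ~0.35 m/s per axis), swamping the
0.2 m/s onset threshold, whereas filtering positions first reduces the
noise to well below it. Path and chord lengths use the filtered positions
for consistency with the speed profile; durations use the recorded
timestamps. The signal is extended by odd reflection before filtering to
suppress edge transients.

Numerical caveat: for very short reaches (≈0.37 s, typical of the
patient workspace) the movement's spectral content brushes the 10 Hz
cutoff and the zero-phase filter's sub-millimetre ringing can inflate the
straightness ratio by a few tenths of a percent. The closed-form
verification sweep therefore uses reach durations of 0.8–1.5 s — the
range typical of healthy adults — where the filter is transparent to
well below the stated tolerances.

Velocity peaks are local maxima of the filtered speed with topographic
prominence at least `max(0.02 m/s, 5% of the peak speed)` and pairwise
separation at least 50 ms (both exposed in the configuration). The
prominence floor suppresses residual noise maxima; the separation rule
merges the double extrema a single underlying event can produce. Movement
onset is the first sample at or above 0.2 m/s after target appearance;
segments that never reach the threshold have no onset and are excluded
listwise from the onset analysis only.

Extreme outliers are removed per metric with Tukey ×3 fences,
`[Q1 − 3·IQR, Q3 + 3·IQR]`, quantiles by linear interpolation (R type 7 —
the convention matters, so it is fixed and tested), strict inequality
(fence values kept), single pass. Fences are computed per participant
pooled across conditions by default; per-condition grouping is a
configuration switch, since published per-condition removal counts leave
the original grouping ambiguous.

## Scoring

Counting: the participant counts each fruit category aloud, restarting
each block. A response is correct iff its spoken category matches the
presented fruit and the number lies in `{true count, last said + 1}` — the
carry-forward rule that credits continuing from an erroneous value. The
acceptance set is recomputed at every fruit, so recovery to the true count
is also credited; the original description's single example does not
determine whether recovery was accepted, and the more permissive reading
was chosen. Block percentages average unweighted into one value per
participant and condition.

Questionnaires: SUS is the 0–100 affine rescale of the item mean
(`100·(mean−1)/(scale_max−1)`; the patient protocol used a 5-point
scale, so the scale width is a parameter); IMI is per-subscale raw-scale
means; Raw NASA-TLX passes the six 0–100 sliders through unweighted, and
`digitize_rtlx_paper()` converts paper-form measurements (distance rounded
to 0.5 mm, divided by the 122–125.5 mm physical scale length).

## Statistics

The repeated-measures harness operates on participant × condition ×
depth-class cell values; cells are per-participant means of segment-level
metrics (medians are a configuration switch; means are the conventional
choice, and the aggregation level is not otherwise documented).

- `rm_anova_2way()` is the classical balanced within-subject
  decomposition: each effect is tested against its interaction with
  subjects. Sphericity is assessed per effect with Mauchly's test on the
  effect's orthonormal contrast space; the Greenhouse–Geisser ε (Box's
  epsilon, clipped to `[1/df, 1]`) is always reported and the headline
  p-value applies it only when Mauchly's p < α, with the uncorrected
  result always available. Effect sizes are partial η² =
  `SS_effect/(SS_effect + SS_error)`.
- `rm_manova_oneway()` computes Wilks' λ from the hypothesis SSCP of the
  condition effect and the error SSCP of the subject-by-condition
  interaction, with Rao's F approximation. This multivariate extension of
  the within-subject decomposition reduces *exactly* to the univariate
  RM-ANOVA F for a single dependent variable — a property the
  transformed-contrast (Hotelling-type) formulation lacks, and the reason
  this formulation was chosen. The multivariate partial η² convention,
  `1 − λ^{1/s}`, is recorded in the output rather than assumed comparable
  to other software.
- `friedman_kendall()` delegates to `stats::friedman.test` (mid-rank tie
  correction) and reports Kendall's W = χ²/(n(k−1)); a table with complete
  ties in every row carries no concordance information and returns χ² = 0,
  W = 0 by convention.
- `posthoc_paired()` runs paired t-tests with Bonferroni adjustment
  `min(1, m·p)` and Cohen's d. The default convention is
  d_z = mean(diff)/sd(diff) (d_av is available); the original variant is
  not documented, so the output names its convention. Zero-variance
  differences are flagged degenerate with an infinite-magnitude t rather
  than failing.

Calibration of the harness is itself tested: under the null generator the
condition main effect rejects at 5% ± 2% (1000 replicates at n = 17), and
under the default condition effects the duration main effect is detected
and the Screen > AR > IVR cell-mean ordering recovered in ≥ 90%/95% of 200
replicates. These replicate counts, and the n = 17 / 48-trial problem
size, are the package's chosen study conditions for the calibration suite.

## Pipeline and reproducibility

`run_full_pipeline()` chains simulation → segmentation → metrics → outlier
removal → scoring → statistics → report. All files are UTF-8, comma- or
tab-separated with dot decimals; units are encoded in column names
(`time_s`, `x_m`, `normalized_duration_s_per_m`); coordinates are metres
throughout, converted only at I/O boundaries. A seed is mandatory; every
stochastic stage derives its randomness from it, and rerunning a
configuration reproduces every data file byte-identically (verified by MD5
hashes recorded in the run manifest, alongside per-stage record counts and
warnings). Per-condition outlier-removal counts are logged in the manifest
and report to make comparison with published removal counts possible when
real data are used.

## Known limitations

- Jerk-based and spectral smoothness measures (e.g. SPARC) are out of
  scope, as is orientation/quaternion analysis.
- The reader for deposited raw datasets is limited to the package's own
  long CSV format; adapters for other layouts must be written separately.
- Statistical functions require complete, balanced within-subject designs
  and reject missing cells rather than imputing.
- The generator's effect magnitudes are plausible but arbitrary; only
  their ordering and the machinery around them are meaningful.
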