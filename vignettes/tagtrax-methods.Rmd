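---
title: "From pose tables to tag-effect tests: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pose tables to tag-effect tests: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagtrax)
```

tagtrax turns multi-landmark pose-tracking tables into three locomotor
traits per animal — average speed, number of walk bouts, and zone
exploration — and tests whether carrying an identification tag shifts those
traits between a tagged and an untagged group. This vignette explains the
processing model, the statistical procedure, the synthetic-trial generator,
and the design decisions behind each, including the ones where reasonable
alternatives existed.

## The processing chain

The input is tracker output: per frame, each body landmark's pixel position
and a confidence (likelihood) in [0, 1]. The chain is fixed:

1. **Confidence masking.** Landmark detections with likelihood strictly
   below the P-cutoff (default 0.6, the tracker's conventional default) are
   treated as missing. A likelihood exactly at the cutoff is kept: the
   cutoff is the *minimum confidence for inclusion*. The tracker ecosystem
   is ambiguous about the boundary case; we fixed the inclusive reading and
   document it rather than leave it implementation-defined.
2. **Centroid.** The animal's location in a frame is the arithmetic mean of
   its unmasked body landmarks (antenna-tip landmarks, when tracked, are
   excluded — they flail independently of body position). A frame needs at
   least `min_valid_landmarks` unmasked landmarks to count. The default is
   *all four* landmarks of the standard rig: validation with the simulator
   showed that averaging a 3-of-4 subset of an asymmetric landmark layout
   offsets the centroid by ~3 mm from the body centre, which differentiation
   turns into ~90 mm/s phantom speed spikes. Rejecting partial frames and
   letting gap interpolation bridge them (dropouts are typically a single
   frame) removes that artifact; set the parameter to 2 to get the
   permissive behavior.
3. **Calibration.** Pixels map to millimetres through per-axis scale factors
   and an origin, supporting slightly anisotropic calibration from separate
   horizontal and vertical reference lengths. Valid points outside the
   arena rectangle are clamped to the boundary with a warning; excursions
   beyond 5 mm usually mean a wrong scale or origin and the warning says so.
4. **Gap interpolation.** Runs of at most `max_gap_frames` (default 15,
   0.5 s at 30 fps) invalid frames flanked by valid ones are filled
   linearly. Longer gaps are left invalid and split the trajectory into
   independent segments for filtering. The upstream literature rarely states
   how gaps were bridged; 0.5 s is short enough that linear filling cannot
   fabricate behavior, and anything longer is treated as genuinely unknown.
5. **Smoothing.** Each coordinate of each contiguous valid segment passes
   through a second-order low-pass Butterworth filter with a 6 Hz cutoff,
   the standard choice in gait analysis for suppressing digitization noise.
   The filter is applied forward and then backward (zero phase) by default:
   phase lag would shift every speed estimate in time and bias bout
   boundaries. The cost is that the effective magnitude response is the
   *square* of the single-pass response — the amplitude gain at the cutoff
   is 1/2, not 1/√2 — which the tests assert explicitly. A single-pass mode
   is available behind `zero_phase = FALSE`. Segments are padded by odd
   reflection (length 3·(2·order + 1)) with steady-state initial
   conditions, so constant input passes through exactly and edge transients
   are suppressed; segments of 3·order frames or fewer pass through
   unfiltered rather than being distorted by a filter longer than the data.
6. **Speed and the biological gate.** Interval speed is the Euclidean
   displacement between consecutive frames times the frame rate. Intervals
   faster than 230 mm/s — the recorded maximum moving speed of *Blaptica
   dubia* — are tracking errors; the *later* frame of each offending
   interval is invalidated in a single pass (no cascade: iterative removal
   could eat a genuine sprint one frame at a time). Exactly 230 mm/s is
   kept (strict gate). Speeds are recomputed once after gating so the
   metrics see interval validity consistent with the final mask.

The frame count is preserved at every stage; all removals are expressed
through the validity mask, never by shortening the series.

## The three traits

* **Average speed** — summed valid inter-frame displacement divided by the
  number of intervals, times the frame rate (mm/s). After frames are
  removed, "total number of frames" becomes ambiguous; the default divides
  by *valid* intervals so that an animal with more masked frames is not
  spuriously slowed down. Dividing by all intervals is available via
  `speed_denominator = "total"`.
* **Walks** — a walk bout is a maximal run of consecutive valid intervals
  each strictly above 10 mm/s (1 cm/s), lasting at least 1 s (inclusive).
  A single sub-threshold or invalid interval ends a bout: the definition is
  *continuous* movement, with no dip tolerance. Bout duration is the number
  of supra-threshold intervals divided by the frame rate — the time
  actually spent moving — so 30 intervals at 30 fps is exactly 1 s and
  qualifies.
* **Exploration** — the arena floor is tiled by an 18-cell grid and the
  trait is the number of distinct cells the centroid visits. The grid shape
  is 3 × 6: with a 185 × 80 mm arena this gives near-square cells
  (~30.8 × 26.7 mm); only the count 18 is fixed by convention, the shape is
  configurable. Cell membership uses `floor` indexing with points exactly
  on the far edges assigned to the last row/column. Frame membership, not
  boundary crossing, defines a visit; at these speeds (≪ one cell per
  frame) the two readings coincide.

## The statistical procedure

Each trait is compared between groups with an ordinary linear model: trait
(possibly transformed) on a two-level tag factor plus the experimental
block factor, both treatment-coded with `untagged` and the first block as
references, so a positive tag coefficient means the tagged group scored
higher. The tag term is tested with a Type II F test (`car::Anova`), which
in a balanced design coincides with the sequential test with tag entered
last — asserted in the tests.

Normality of residuals is checked with a Shapiro–Wilk test. When it fails
(p < α), the trait is re-analysed along a transformation ladder: identity,
then √x, then log x, then x³, stopping at the first rung whose residuals
pass; if none passes, the last rung is reported with a non-normality flag.
Two fixed presets reproduce published per-study choices: `"rfid"` (√ for
all traits) and `"marker"` (identity for speed, log for walks, x³ for
exploration). "Cube transformed" is read literally as x³ — a reported
standard error of several hundred on an 18-bounded count is only consistent
with the cubed scale — but x^(1/3) is available as `"cuberoot"`. Counts of
zero under the log rung receive a +0.5 half-count offset, announced loudly.
No multiple-testing correction is applied across the three traits,
matching the published procedure; a Holm adjustment can be applied by the
user to the returned p-values if desired.

Blocks are modeled as fixed effects: with 2–4 blocks there is no basis for
estimating a variance component. If a block contains only one group the
design is singular in the interaction sense and the block term is dropped
with a warning rather than silently aliasing the tag effect.

## The trial simulator

Because raw videos of the motivating studies are not available, validation
relies on a generator with known ground truth. An animal alternates
exponentially-distributed pauses (mean 20 s) and walks (mean 3 s); each
walk draws a gamma-distributed bout speed (mean 25 mm/s, shape 4) and
performs a correlated random walk (per-frame heading noise, sd 0.4 rad)
inside the 185 × 80 mm arena. Near a wall (within 20 mm) the heading is
blended toward the wall tangent with weight 0.7 — a cheap implementation of
thigmotaxis that reproduces edge-dwelling without a potential-field model;
a step that would exit the arena steers along the wall instead. Tagged
individuals multiply their walk-initiation rate and bout speed by the
effect parameter. Observation noise is layered on top: four zero-mean
body-frame landmarks rotated by the heading, converted to pixels
(0.25 mm/px), Gaussian per-landmark jitter (1 px), and likelihood dropout
(2% per landmark-frame).

These parameter values are the generator's fixed study conditions. Under
the null they give ≈ 3 mm/s average speed, ≈ 35 walks, ≈ 14–17 zones per
20-min trial — an animal more active than the published untagged groups
(≈ 0.7–1.2 mm/s, 2–4 walks). The generator is a renewal-process emulation
of the *structure* the metrics assume, not a calibrated model of *B.
dubia* biology: no distributional information about real bout durations or
speeds exists to calibrate against, and the defaults were chosen once to
exercise every code path (many bouts per trial, bouts straddling the
1 cm/s threshold, wall-following) rather than revisited.

**Ground truth is defined through the measurement chain.** A trial's true
traits are computed by running the deterministic part of the chain
(smoothing, speeds, metrics) on the noise-free path. The 6 Hz smoother is
part of the trait definition: it shortens a twisting path by a few percent
(corner cutting) and shifts threshold crossings at bout boundaries, so
"truth" defined on the raw path would differ from any noise-free
measurement by filter effects rather than by observation error. With truth
defined this way, zero-noise recovery through the full render → ingest →
kinematics → metrics chain is exact (asserted for walk and zone counts,
and to < 0.5% for average speed), and discrepancies under noise isolate
exactly the effect of jitter and dropout. The renewal process's raw bout
list is also recorded for reference.

## What the simulation tests do and do not show

The generator emulates the statistical structure the analysis assumes —
bout-structured movement, wall bias, landmark-level noise — but not
biomechanics (no gait, no body flexion), no climbing or vertical behavior,
no between-individual heterogeneity (every simulated animal shares the
same renewal parameters), and white rather than temporally correlated
tracker noise. Two consequences are worth stating plainly, since the test
suite reports them honestly:

* **White jitter inflates average speed.** Filtered 1 px jitter leaves
  ~0.07 mm frame-to-frame position noise; differentiation at 30 fps
  rectifies this into ~1.8 mm/s of apparent speed on the ~87% of frames
  where the animal is actually paused — a large relative bias on trials
  whose true mean is ~3 mm/s. No 6 Hz linear filter can remove it. Real
  tracker error is temporally smoother than white noise, so this is a
  conservative stress test; the noisy-recovery test records the measured
  bias rather than pretending a tight bound is met. The same mechanism
  fragments low-speed bouts (noise dips below the strict 10 mm/s
  threshold), so bout counts recovered under white noise scatter by more
  than ±1.
* **Homogeneous animals make tiny standard errors.** With no
  between-individual variance beyond renewal stochasticity, even a ×1.25
  tag multiplier is detected almost surely at n = 10 + 10. The published
  null result for RFID tags at that sample size reflects biological
  variance the generator deliberately does not model; the simulator can
  show calibration under the exact null (effect = 1) and power under
  strong effects, but cannot reproduce "small real effect, large real
  variance" non-significance.

## Numerical choices and degenerate inputs

Problem sizes in the validation suite were chosen to give stable Monte
Carlo estimates at interactive runtimes: 1,000 random series for the
walk-detection oracle, 100 random fixtures for the OLS/F oracle (agreement
to 1e-8), 50 zero-noise and 200 noisy recovery trials, 500 replicate
studies for type-I calibration (binomial SE ≈ 0.01 at α = 0.05), and 200
replicates per power condition. Seeds are fixed in tests; every
user-facing stochastic entry point takes an explicit seed, and
per-individual seeds are derived from the study seed so any trial can be
regenerated in isolation.

Degenerate inputs are defined rather than accidental: an empty pose series
passes through the cutoff unchanged; a trial with no valid interval yields
`NA` average speed and a flagged row; a constant residual vector is a
normality-check error (the statistic is undefined); a filter cutoff at or
above Nyquist is a configuration error; a single-frame trajectory has an
empty speed series. Ties at thresholds are all fixed conventions, tested
explicitly: likelihood *equal* to the P-cutoff is kept, speed *equal* to
the walk threshold is not walking, speed *equal* to the gate is kept, bout
duration *equal* to the minimum qualifies, a point *on* the far arena edge
belongs to the last zone.

## Known limitations

Single-animal trials only (no identity tracking); 2-D arena (climbing
attempts in real trials appear as brief tracking noise, not as a modeled
behavior); fixed processing order (cutoff → centroid → calibrate →
interpolate → filter → gate), with only the filter-then-gate order being
externally fixed — the rest is this package's documented convention; and
the average-speed metric inherits the rectified-noise bias of any
frame-differentiated position signal, which should be kept in mind when
comparing absolute speeds across tracking setups with different noise
levels. Group comparisons assume one trial per individual; repeated
measures would need a mixed model, deliberately out of scope.
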