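# tagtrax

Post-processing and tag-effect analysis for animal pose-tracking
trajectories.

Attaching an identification tag (an RFID transponder, a printed
machine-readable label) to an insect can itself change the behavior the tag
is meant to help measure. tagtrax implements the full analysis chain used
to test for such effects in open-field trials of *Blaptica dubia*
cockroaches tracked with markerless pose estimation: it consumes
DeepLabCut-style landmark tables and a trial manifest, produces calibrated
centroid trajectories and three locomotor traits per animal, and compares a
tagged and an untagged group with a transformation-aware linear-model
procedure. A correlated-random-walk trial simulator with known ground truth
makes every stage testable without raw videos.

## What it computes

**Processing chain** (per trial): confidence masking at the tracker
P-cutoff (default 0.6, inclusive at the boundary) → centroid = mean of the
unmasked body landmarks → pixel-to-mm calibration → linear interpolation of
gaps ≤ 0.5 s → zero-phase 2nd-order low-pass Butterworth smoothing at 6 Hz
→ inter-frame speeds → removal of frames reached faster than 230 mm/s (the
species' recorded maximum).

**Traits** (per animal):

- average speed `v̄ = (Σᵢ ‖xᵢ₊₁ − xᵢ‖ / n_intervals) · fps` (mm/s);
- number of walks, a walk being a maximal run of intervals with speed
  > 1 cm/s lasting ≥ 1 s;
- exploration, the number of distinct cells of a 3 × 6 tiling of the
  185 × 80 mm arena floor visited by the centroid.

**Group comparison** (per trait): OLS of the (possibly transformed) trait
on tag + experimental block, treatment-coded with untagged as reference;
Type II F test for the tag factor (`car::Anova`); Shapiro–Wilk residual
check with an identity → √ → log → x³ transformation ladder, or the fixed
per-study presets `"rfid"` (√ everywhere) and `"marker"` (identity / log /
x³). Positive effect sizes mean the tagged group scored higher.

## Worked example

Simulate a marker-study-scale experiment (15 tagged + 15 untagged animals
in 4 blocks, a strong ×5 tag effect on walk initiation and speed), observe
it through the noisy tracking model, and run the comparison:

```r
library(tagtrax)
st <- simulate_study(15, 15, 4, effect = 5, seed = 2024)
set.seed(7)                      # rendering noise
m  <- compute_study_metrics(st, observe = "noisy")
study <- run_study(m, preset = "auto")
study
#> Tag-effect study (auto transformations, alpha = 0.05)
#> Effect sizes are tagged - untagged on the analysis scale;
#> group means are on the original scale.
#>
#>             trait transformation effect_size std_error f_value df_num df_den
#>    avg_speed_mm_s       identity       42.70     0.972  1930.0      1     25
#>           n_walks       identity       92.10     2.850  1040.0      1     25
#>  n_zones_explored       identity        2.69     0.454    35.1      1     25
#>   p_value shapiro_p mean_untagged mean_tagged significant
#>  3.42e-25     0.150          4.76        47.5        TRUE
#>  6.58e-22     0.399         33.20       126.0        TRUE
#>  3.48e-06     0.120         15.30        18.0        TRUE
```

All three traits are significantly higher in the tagged group
(`effect_size > 0`, `p_value < 0.05`): the tagged animals moved ~10× faster
on average, walked ~4× more often, and saturated the 18-zone exploration
ceiling. `plot(study)` draws the per-group box plots with mean markers.
(The shapiro_p column shows the residual-normality p at the selected
transformation; exact values vary with the rendering seed.)

The file-based route does the same from disk: `write_study(st, "study/")`
emits DeepLabCut-format CSVs plus a manifest, and
`run_pipeline("study/manifest.csv", "out/")` writes per-trial calibrated
trajectories, the metrics table, the comparison table, figures, and a run
record embedding the exact configuration.

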