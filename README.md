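# pursuitmon

Analysis pipeline for continuous action-monitoring experiments based on
pursuit tracking. A participant follows a moving target along an invisible
sum-of-sinusoids trajectory with a joystick-driven cursor; behavior is
recorded at 60 Hz and EEG at 250 Hz. The package covers the full analysis
chain for the two standard task variants (online adaptation with a repeated
middle trajectory segment; intermittent cursor occlusion), together with a
synthetic-data generator with known ground truth so that every stage is
testable without the original recordings.

## What it computes

**Task design.** Trajectory segments are three-harmonic Fourier series
f(x) = Σᵢ aᵢ sin(i·x) + bᵢ cos(i·x) (i = 1..3), the repeated segment with
fixed coefficients a = (37, −3, 26), b = (23, −15, −9) px, random segments
with coefficients uniform on [−40, 40] px, joined across 30-px gaps by cubic
splines; counterbalanced 72-trial sessions (2 directions × 3 velocities × 12).

**Behavior.** Epoch error (RMSE between target and cursor) and pursuit
latency (delay from a target direction change to the following same-direction
cursor direction change, valid in 80–300 ms) from prominence-thresholded peak
detection (1% / 5% of screen size) after cubic-spline upsampling to 250 Hz;
3-SD outlier-trial flagging; sample entropy SampEn(m = 2, r = 0.2 SD) of the
z-scored tracking error, comparing the first 500 ms of each trial with the
following 1500 ms via a Wilcoxon rank-sum test with effect size r = Z/√N.

**Vincentile statistics.** Ten equal-populated bins per subject × condition,
bootstrap paired t-tests per bin (5000 resamples, α = 0.001),
Benjamini–Hochberg FDR at q = 0.05, paired Cohen's d, and cross-sorting of
epoch error by pursuit-latency vincentiles.

**EEG.** Morlet band power (width 5 cycles; theta 4–7, alpha 8–12, beta
13–30 Hz) with decibel baseline against −750–0 ms; condition segmentation;
cluster-based permutation tests (pointwise paired t at cluster-α = 0.001,
spatio-temporal clustering, sign-flip null, 1000/3000 iterations); normalized
source contrast (p₁ − p₂)/(p₁ + p₂) with DBSCAN voxel clustering of the
extreme 1% tail; peak-locked ERP analysis from −500 to 750 ms with
spherical-spline current source density, trial-count weighting, cluster
selection rules (top-3 per polarity, ≥5 samples, onset ≤300 ms), peak-latency
contrasts, and the 10 × 10 ERP-by-performance vincentile matrix
(50-ms bins from 50 to 550 ms).

## Worked example

```r
library(pursuitmon)

# a synthetic task-1 study: 6 subjects, 12 trials each
study <- make_study(n_subjects = 6, task = 1, seed = 1, n_trials = 12)
m <- study$metrics
round(100 * mean(m$valid), 1)               # % epochs with valid pursuit latency
#> [1] 74.2
round(1000 * median(m$pursuit_latency_s[m$valid]))   # median latency, ms
#> [1] 188

# sample-entropy interval analysis of the tracking error
errors <- unlist(lapply(study$subjects, function(s) {
  lapply(s$trials, function(tr) tr$trajectory$y - tr$cursor_y)
}), recursive = FALSE)
subj <- rep(seq_along(study$subjects), each = 12)
ent <- entropy_interval_test(errors, subj)
round(c(first = ent$median_first, second = ent$median_second,
        Z = ent$Z, r = ent$effect_r), 3)
#>  first second      Z      r 
#>  0.123  1.254 -2.991 -1.221 

# vincentile contrast of epoch error, constant vs random segments
cond <- m[m$condition %in% c("constant", "random"), ]
tab <- vincentile_table(cond, "epoch_error_px")
ct <- vincentile_contrast(tab, "constant", "random", n_boot = 2000, seed = 2)
round(ct$t_per_bin, 2)
#>  [1]   3.70   2.62  -0.93  -6.68 -13.09  -9.62 -10.74 -10.22  -8.40  -6.43
ct$fdr_mask
#>  [1]  TRUE FALSE FALSE  TRUE  TRUE  TRUE  TRUE  TRUE  TRUE  TRUE
```

The entropy analysis shows the generator's designed structure: during the
first 500 ms the simulated cursor has not started moving, so the error trace
is target-driven and smooth (low sample entropy), while the later interval is
dominated by motor noise (much higher entropy) — hence the strongly negative
rank-sum Z (−2.99 is the largest magnitude attainable with 6 subjects per
group). The epoch-error contrast is negative in the upper vincentiles: in
this synthetic study the first random segment includes the post-dead-time
catch-up sweep, so the largest errors live in the random condition, and the
constant-minus-random difference grows more negative toward the high-error
bins.

A command-line front end wrapping the same functions is installed with the
package at `inst/cli/pursuitmon` (subcommands `design`, `synth`, `behavior`,
`vincentiles`, `run-all`).

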