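---
title: "Analysing continuous pursuit tracking: behavior, entropy, vincentiles and EEG cluster statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing continuous pursuit tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experimental paradigm

`pursuitmon` implements an analysis chain for continuous action-monitoring
experiments built on pursuit tracking: a participant follows a steadily moving
target along an invisible vertical trajectory with a joystick-driven cursor
while behavior (60 Hz) and EEG (250 Hz, 60 channels) are recorded. Two task
variants are covered: an online-adaptation task in which the middle trajectory
segment is repeated in every trial while the flanking segments are random, and
an occlusion task in which the cursor disappears for 2 s of every 4 s cycle,
starting visible.

Each trajectory segment is a three-harmonic Fourier series

$$f(x) = \sum_{i=1}^{3} a_i \sin(i\,x) + b_i \cos(i\,x),$$

with the repeated segment fixed at $a = (37, -3, 26)$, $b = (23, -15, -9)$
pixels and random segments drawing all six coefficients uniformly from
$[-40, 40]$ px, rejected and redrawn if the excursion would leave the screen.
Segments are separated by a 30-pixel horizontal gap bridged with an
interpolating cubic spline. A session crosses 2 movement directions with 3
target velocities, 12 repetitions each (72 trials), with uniform 1–2 s
fixation pauses and a 30-s break every 10 trials.

Several geometric details of the paradigm are not fully specified by its
public description and were fixed here as package defaults, all configurable
through `study_config()`:

* screen: 1920 × 1080 px; "screen size" for prominence thresholds is the
  vertical extent (1080 px);
* velocity levels map to trial durations of 13.5, 12 and 10.5 s, so the mean
  trial lasts 12 s; the trajectory parameter $x$ advances linearly with the
  target's horizontal position, one $2\pi$ period per segment;
* the start vector is a 500 ms straight run at screen-centre height whose
  final 250 ms ease cubically onto the first segment sample, keeping the
  trace continuous;
* left-moving trials mirror the horizontal axis only;
* fixation durations are uniform on $[1, 2]$ s (mean 1.5 s);
* the occlusion cycle is 2 s visible / 2 s occluded. The paradigm's two
  published descriptions of this cycle disagree ("2 s every 4 s" vs "2 s
  every 2 s"); the alternating 2 s/2 s reading satisfies both and is used.

## Synthetic data as the test bed

Because every stage must be testable without the original recordings, the
package ships a first-class generator (`make_study()`, `simulate_cursor()`,
`simulate_eeg()`) whose defaults are the study conditions: 30 subjects and the
72-trial session plan.

The cursor model is a deliberately minimal first-order tracker: the cursor
rests at screen centre for a 500 ms dead time (participants typically do not
move the joystick at trial start), then follows a lag-shifted (default
150 ms), exponentially smoothed copy of the target with additive Gaussian
motor noise (default SD 8 px, scaled ×1.5 during occlusion). The model was
chosen for its analytic cross-correlation structure — an injected lag is
exactly the cross-correlation peak — which makes parameter-recovery tests
sharp: the downstream pursuit-latency estimate must recover the injected lag
to within one frame (16.7 ms) in the noise-free case.

Synthetic EEG is built from three ingredients with a ground-truth manifest:
$1/f$ noise (spectral shaping, default exponent 1), band-limited oscillations
(theta/alpha/beta carriers at 5.5/10/20 Hz) whose amplitudes scale per
condition inside declared condition windows, and an ERP template added at each
target direction change. The montage is a deterministic golden-angle spiral of
60 positions on the upper unit sphere, standing in for the equidistant
10%-system cap.

What the generator does *not* emulate: biophysically realistic source mixing
and volume conduction, eye movements, learning across trials, non-stationary
noise, or channel artifacts. Passing tests therefore demonstrate that the
analysis chain is correct and calibrated on data with the designed statistical
structure — not that it is robust to every pathology of real recordings.

## Behavioral measures

Traces are upsampled from 60 to 250 Hz with cubic splines before analysis.
The analysis unit ("epoch") is a window (−500 to 750 ms) around each target
direction change. Two measures are computed per epoch:

* **epoch error** — the RMSE between target and cursor height;
* **pursuit latency** — the delay from a trajectory peak to the following
  cursor peak, valid when it falls within 80–300 ms and both peaks have the
  same direction. Peaks are local extrema with a topographic prominence of at
  least 1% (target) or 5% (cursor, which is noisier) of the screen size.
  Matching is one-to-one and takes the earliest in-window same-direction
  pursuit peak — the latency is defined as the time to the *following*
  matching direction change, so earlier candidates take precedence.

Trials whose maximum absolute error exceeds the within-subject mean by more
than three standard deviations of the per-trial maxima are flagged
(`exclude_outlier_trials()`), automating a manual-inspection step; when the SD
is zero, nothing is flagged.

The early-trial analysis computes sample entropy, SampEn$(m, r) =
-\ln(A/B)$ with template length $m = 2$, Chebyshev distance and similarity
criterion $r = 0.2$ SD (matches counted with $\le r$, self-matches excluded),
on the signed tracking error of the 0–500 ms and 500–2000 ms intervals, each
z-scored per trial so the same criterion applies everywhere. Per-trial values
are reduced per subject by the median (the mean is available; the reducer is
not pinned down by the published description) and the two intervals are
compared with a Wilcoxon rank-sum test, reported as $Z$, $p$, and $r =
Z/\sqrt{N}$ with $N$ the number of subjects. The rank-sum (unpaired) test is
used as published even though the design is paired; a signed-rank variant sits
behind `test = "signed_rank"`. Trials whose interval has zero variance are
skipped and counted; intervals whose entropy is infinite (no matching
template pair, possible in very short noisy intervals) are dropped in the
per-subject reduction.

## Vincentile statistics

Condition contrasts of the skewed behavioral measures use vincentiles: the
values of each subject × condition are sorted and split into $k = 10$
equal-populated bins, and bin means are compared across subjects. When the
count is not divisible by 10 the remainder goes to the lowest bins — a
deterministic rule; populations never differ by more than one. Each bin is
tested with a paired two-tailed bootstrap t-test (5000 resamples, α = 0.001):
the observed paired t is compared against t statistics of subject resamples
drawn with replacement from the H0-centred differences, with add-one
smoothing. The published mechanics name only "bootstrap samples"; centring
under H0 was chosen because it yields a valid null distribution for a t
statistic, and a percentile-of-differences variant is available behind
`method = "percentile"`. Resampling is over subjects, matching the
description of sampling "from the subject sample data". The ten p values per
contrast receive Benjamini–Hochberg FDR control at $q = 0.05$
(`stats::p.adjust`). Cohen's d is the paired mean(diff)/sd(diff).
`cross_sort()` bins epoch error by the pursuit-latency vincentiles to expose
the association between the two measures.

## Time-frequency and cluster statistics

Band power uses complex Morlet wavelets with a width of 5 cycles, in 1 Hz
steps across theta (4–7 Hz), alpha (8–12 Hz) and beta (13–30 Hz). Power is
expressed relative to the −750–0 ms pre-trial baseline; the baseline mode is
decibel change (robust to multiplicative noise), with a plain ratio mode
configurable. Trial TFRs are segmented into the condition windows: for task 1
the first interval takes the initial 500 ms of the random and of the constant
segment, the second interval compares 500–3000 ms of the random segment with
0–2500 ms of the constant segment (equal 2500 ms windows, as specified even
though the random segment spans to 3000 ms); for task 2, alternating 2-s
occluded/visible windows beginning visible.

Condition contrasts use cluster-based permutation tests: pointwise paired
t-tests thresholded two-sidedly at cluster-α = 0.001, supra-threshold points
grouped by spatial adjacency plus time/frequency contiguity, clusters scored
by summed t values, and the null distribution built from within-subject sign
flips (1000 iterations for TFR contrasts, 3000 for ERPs). Three numerical
choices deserve note:

* **Adjacency** is distance-based: channels are neighbours when closer than
  1.6 × the montage's median nearest-neighbour distance (configurable). A
  triangulation-based neighbourhood would be an alternative; the distance
  rule was chosen because it is transparent, parameter-light and easy to
  reproduce.
* **Two-sided reference distribution.** Cluster p values compare |t sum|
  against the permutation maximum of |cluster sum| across *both* polarities.
  Comparing each polarity only against its own extreme distribution doubles
  the family-wise error of a two-sided test (we measured ≈10% empirical FWE
  at nominal 5% on null data); the combined reference controls it at α.
* **Sign-flip permutations** are exact for paired designs under symmetric
  null differences; the permutation scheme of the original toolbox is not
  spelled out beyond its name.

Source-level contrasts are consumed as generic voxel power maps: the
normalized ratio $(p_1 - p_2)/(p_1 + p_2)$ (bounded, zero-sum voxels map to
0), the extreme 1% tail in the direction of interest, and density-based
clustering with a search radius of 1.5 × the voxel edge length. The
minimum-neighbour count of the density clustering is not published; the
default is 5, configurable. Beamforming itself (forward models, spatial
filters) is out of scope.

## ERP analysis

EEG is epoched from −500 to 750 ms around trajectory peaks (313 samples at
250 Hz), baseline-corrected on the first 500 ms. A spherical-spline surface
Laplacian (`csd_transform()`, stiffness m = 4, regularization λ = 1e−5,
50 Legendre terms, unit head radius — the cited toolbox defaults) sharpens
topographies; it is linear and maps uniform potentials to zero, which the
tests exploit. Subjects are weighted by median(epoch count)/own count before
grand averaging. The ERP cluster test additionally discards clusters that
never span at least four electrodes at a single time point; cluster selection
keeps at most the three largest clusters per polarity by |t sum| (the
scree-plot elbow rule), then drops clusters shorter than five samples or with
onset later than 300 ms (after which activity mixes with the following
direction change). Peak-latency contrasts search 200–450 ms by default
(bracketing the component means of ~290 and ~345 ms reported for this
paradigm; the window itself is not published). The published df of 35.99 for
that latency test is inconsistent with a paired test on 30 subjects; the
package implements the plain paired t-test as described.

The ERP-by-performance association grids epochs (valid-latency only,
cluster electrodes only) into 10 behavioral vincentiles × 10 time bins of
50 ms from 50 to 550 ms (12–13 samples per bin at 250 Hz), tests each of the
100 cells with the bootstrap paired test, and applies BH-FDR across the 100
p values per contrast (per-contrast rather than global correction; the
published description does not distinguish the two).

## Problem sizes used in tests and the acceptance script

The shipped checks run the full method code on scaled problem sizes chosen to
exercise every code path with tight statistical tolerances: calibration
studies use 15–30 subjects on 16-channel, 100–500-sample grids; the
alpha-power detection study uses 30 subjects, two 2-s trials per condition,
alpha amplitudes of 4 vs 3 µV on six adjacent channels over 1/f noise of 8 µV
SD — a subject-level effect size near 0.9, i.e. "moderate SNR" in the sense
that single subjects are far from ceiling while the 30-subject test has high
power. The synthetic study in `scripts/acceptance.R` uses 30 subjects × 12
trials; all quantities it reports are computed at run time from these
simulations.

## Known limitations

* The behavioral "epoch" definition (window around each trajectory peak) and
  the per-subject entropy reducer are interpretations of an under-specified
  description; both are configurable.
* Sample entropy on 30-sample intervals is a high-variance estimator and can
  be infinite for unstructured intervals; downstream aggregation is robust
  (median, non-finite dropped) but single-trial values should not be
  over-interpreted.
* With the default generator settings the cursor's 500 ms dead time coincides
  exactly with the 500 ms start vector, so the z-scored first-interval error
  shape — and hence its sample entropy — is almost identical across trials.
  The interval contrast is therefore sharper in synthetic data than it would
  be in recordings, where dead times vary around the trajectory onset.
* The EEG preprocessing chain (filtering, ICA, channel repair) is out of
  scope; the package expects cleaned data.
* DICS beamforming, sLORETA and atlas lookup are out of scope; source-level
  operations start from voxel power maps.
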