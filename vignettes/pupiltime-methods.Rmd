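---
title: "Temporal pupillometry and gaze analysis: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal pupillometry and gaze analysis: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pupiltime)
```

## What this package computes

`pupiltime` implements a complete analysis chain for event-related
pupillometry and gaze behavior recorded at 300 Hz during short (4.5 s)
naturalistic emotion-expression videos, in a two-group design (an ASD-like
and a TD-like group in the synthetic data; any two groups in general):

1. **Pupil preprocessing** — from raw binocular diameter samples to a
   baseline-corrected trial response.
2. **Fixation detection** — Savitzky–Golay denoising, angular velocity, an
   adaptive (data-driven) saccade threshold, duration filtering.
3. **AOI outcomes** — eye/mouth region assignment, fixation counts and mean
   durations, and looking time summed in 50 ms bins as a temporal
   progression measure.
4. **Pupil time components** — PCA over the pooled trial × time matrix,
   varimax rotation, and serial time windows (T-RC1..3) defined by the
   highest-loading time points; pupil dilation (PD) is the mean response
   per window.
5. **Mixed models** — PD-by-window, gaze-outcome, growth-curve
   (polynomial-time) and PD–gaze association LMMs with Tukey post-hocs.

A ground-truth-labelled generator (`simulate_dataset()`,
`sim_looking_bins()`) emulates the whole design so that every stage can be
validated against known truth without participant data.

## Pupil preprocessing

The chain, per eye and in order: removal of off-screen samples; exclusion
of implausible diameters (outside \[2, 8\] mm, strict inequalities);
dilation-speed outliers (speed = max of the absolute slopes to the previous
and next valid neighbour, normalized by the actual time deltas; samples
above `median + 3·MAD` removed); removal of samples within 25 ms of either
end of blink-like gaps (missing runs of 75–250 ms); and a two-pass
trend-line filter (centered 250 ms moving-average trend over valid samples,
residuals beyond 3·MAD removed, trend re-estimated, removal repeated). The
eyes are then combined (the constant inter-eye offset estimated on mutually
valid samples; one-eye gaps filled from the other eye ± offset; per-sample
mean), interior gaps of at most 300 ms are linearly interpolated, a 30 ms
centered moving average smooths the result, and the mean over the first
500 ms is subtracted (baseline correction). Trials with less than 50% valid
samples after preprocessing are excluded; the first 500 ms are excluded
from analysis.

Numerical choices worth knowing:

* **MAD is raw** (unscaled, no 1.4826 consistency factor), matching common
  pupillometry practice for these filters.
* **MAD floor.** The robust spread of a *noiseless* smooth series collapses
  toward zero, at which point a median±3·MAD rule starts excising genuine
  signal curvature (about 1–2% of any continuous slope distribution lies
  beyond that fence). All MAD-based thresholds are therefore floored at
  `mad_floor_mm = 0.002` mm — the order of the diameter quantization step
  of research-grade video trackers. The floor is an order of magnitude
  below the spread produced by realistic measurement noise, so it only
  matters in the (synthetic) noise-free regime, where it keeps the filters
  inert, as they should be when there is nothing to remove.
* **Gap durations** are measured as missing-time span:
  `t(next valid) − t(last valid) − nominal dt`. An n-sample run at 300 Hz
  thus has duration n·10/3 ms, and the printed rule boundaries (75, 250,
  300 ms) correspond exactly to integer run lengths (a 90-sample run is a
  300 ms gap and is still interpolated; a 30-sample run is a 100 ms blink).
* **Ordering.** The artifact filters run per eye; interpolation and
  smoothing run on the combined trace. The valid fraction is counted
  against all nominal samples of the 4.5 s window.

## Fixation detection

Gaze is combined across eyes with the same offset-aware contract as the
pupil (per coordinate), denoised with a Savitzky–Golay filter (order 2,
20 ms window → 7 samples at 300 Hz; missing runs break the filter window),
and converted to angular velocity by central differences under a
flat-screen small-angle model (0.51 m × 0.287 m screen at 0.65 m viewing
distance by default; all configurable). The saccade threshold is data
driven: starting from 100 deg/s, `T ← mean + 6·SD` of the velocities at or
below `T`, iterated to a 1 deg/s tolerance, per trial (stimuli differ, so
thresholds are trial-wise). Runs of sub-threshold samples are candidate
fixations; durations outside \[100, 2500\] ms are excluded; the location is
the mean gaze over the run.

Two boundary effects are intrinsic to these definitions and are accounted
for in validation rather than hidden: central differences and the 7-sample
SG window contaminate roughly 4 samples at each fixation–saccade junction,
so detected durations run ~27 ms short of truth; and at zero noise the
adaptive threshold's SD comes entirely from saccade-ramp tails, so the
converged threshold can sit high enough that a small within-AOI saccade
(amplitude ~0.01 of the screen) genuinely cannot separate its flanking
fixations. The tests therefore compare detection against *detectable*
truth: events filtered by the eroded duration bound and merged across
sub-threshold saccades.

## AOI outcomes

Eye and mouth rectangles span 23% of each screen axis, are aligned on the
x-axis and fixed across stimuli; membership is inclusive on the left/top
edge and exclusive on the right/bottom edge, so boundary points get exactly
one label. Fixation outcomes use the fixation's mean location. Looking time
uses *all* gaze samples (not only fixation samples), counted per 50 ms bin
and AOI over 500–4500 ms (80 bins); bin counts over
{eyes, mouth, other, offscreen} sum to the nominal samples per bin, and
rebinning at 100/200 ms preserves totals exactly. Covariates: onscreen time
(fraction of session samples on screen) and gaze deviation (mean Euclidean
distance of on-screen gaze from screen center; the operational definition
chosen here).

## Pupil time components

Retained trials are resampled to a 10 ms grid over 500–4500 ms (cell
means; rows with any missing cell are dropped) and pooled across all
participants into one matrix — one decomposition for the whole sample.
PCA is covariance-based (the traces share units and their variance profile
over time is the signal of interest; a correlation-matrix option exists).
The top three loading vectors (eigenvector × singular value) are
varimax-rotated with Kaiser normalization; rotation redistributes but
preserves the retained variance (checked to 1e-8). Each time point is
assigned to the component with the maximal absolute rotated loading;
enclaves shorter than 50 ms are absorbed; each component keeps its longest
contiguous run; the runs partition the grid and are relabelled in temporal
order (T-RC1 earliest). The component count defaults to 3 — automated in
place of visual scree inspection — and the full scree is emitted so a user
can override.

## Mixed models

All models: participant random intercept, covariates age, sex and onscreen
time (PD models add gaze deviation), continuous variables centered and
scaled, sum-to-zero factor contrasts, REML estimation, marginal (type III)
tests with Satterthwaite denominator df (or an asymptotic Wald χ²
alternative where the Satterthwaite machinery is needlessly expensive at
10⁵ rows), Tukey-family post-hoc contrasts via estimated marginal means.
Growth-curve models use *orthogonal* polynomials of bin time (numerical
stability; coefficients of different degrees are uncorrelated), fully
crossed with group × AOI × emotion; post-hoc group contrasts are evaluated
every 250 ms by projecting the polynomial basis onto the raw times.
Degree comparison refits at ML and recommends the highest degree whose
likelihood-ratio increment over the previous degree is significant.

**Random-effect structure.** 50 ms bins are strongly serially dependent
within a fixation (~6 bins share one fixation), and eyes/mouth counts are
negatively correlated within a participant (a sample spent on the eyes is
not spent on the mouth). A participant-intercept-only LMM treats the bins
as conditionally independent and dramatically overstates the precision of
group trajectory contrasts: under the package's own null generator the
nominal-5% group × AOI × linear-time test rejects an order of magnitude
too often (the acceptance checks measure the calibrated structure's rate).
The growth-curve default is therefore diagonal by-participant random
slopes over the time polynomials and their products with a numeric AOI
contrast, which lets the eyes-vs-mouth trajectory difference carry its own
between-participant variance and restores calibration;
`random = "intercept"` reproduces the conventional structure for
comparison. This is a deliberate design choice of this package.

## The synthetic generator

The generator is the package's study-condition definition, not a tuning
knob:

* **Design**: 2 groups × 30 participants × 12 trials (4 actors × 3
  emotions), 4.5 s trials at 300 Hz with 2 s fixation-cross gaps.
* **Scanpath**: a semi-Markov AOI process — at each fixation onset the
  target region (eyes/mouth/other) is drawn from logistic-in-time
  preference weights, a target point is drawn inside the region, the
  fixation duration is lognormal (median ≈ 300 ms, σ_log 0.35), and a
  30 ms cosine-ramp saccade leads to the next target. Gaze jitter is
  Gaussian (SD 0.003 of the screen, ~0.14 deg) with a constant binocular
  disparity. The TD-like group's eye preference is roughly flat (0.40 →
  0.50); the ASD-like group starts mouth-dominant (eyes 0.20, mouth 0.48)
  and reverses (eyes 0.55, mouth 0.23) with midpoint 2.2 s — producing the
  crossing looking-time curves that the growth-curve stage must detect.
  Happy expressions shift preference slightly toward the mouth, fear
  toward the eyes.
* **Pupil**: participant baseline N(4.5, 0.35) mm; three gamma-shaped
  kernels (peaks ≈ 0.65, 1.5, 3.4 s) scaled by trial amplitudes with means
  (0.02, 0.06, 0.10) mm — PD rises over the trial — and SDs (0.05, 0.08,
  0.10) mm. Kernel placement and amplitude spreads were chosen so that the
  amplitude-weighted dominance windows switch at ≈ 920 and ≈ 2470 ms,
  i.e. the serial window layout the analysis expects to find. AR(1) noise
  (φ 0.98, innovation SD 0.003 mm → stationary SD ≈ 0.015 mm, the scale of
  post-smoothing tracker noise); the right eye adds a constant individual
  offset and independent white noise. Group effects on pupil amplitudes
  default to **zero** (a null), with nonzero values available for power
  studies; a negative coupling (−0.04 mm per SD) ties the early amplitude
  to the trial's mouth-preference deviation, giving the association stage
  a known sign to recover.
* **Artifacts**: blinks (missing runs of 75–250 ms in pupil and gaze,
  8/min, non-overlapping), single-sample diameter spikes (±0.5–1.5 mm,
  4/min), slow Gaussian drift excursions (±0.4–0.8 mm, ~500 ms scale,
  1/min). All injected indices are recorded in the truth object.

What the generator does **not** emulate: luminance changes (the paradigm
assumes constant luminance), smooth pursuit, pupil foreshortening by gaze
angle, head movement, or tracker-specific noise spectra. Passing tests on
this generator therefore validate the pipeline's *contracts and
statistical behavior*, not its robustness to every property of real
infant eye-tracking data.

## Validation problem sizes

The test-suite and acceptance checks run at sizes chosen to make each
property measurable while keeping a full run practical on a laptop: oracle
equivalence on 200 randomized 50-sample traces per filter; fixation
recovery on 50 trials; component recovery on 360 trials; type-I
calibration of the growth-curve interaction on 200 null replicates at
n = 30/group with 200 ms bins and the linear-time model (the bin width
affects only the resolution of the test, not its calibration target); sign
recovery on 20 replicates at the generator defaults; degree selection on
50 replicates of a cubic time course at n = 30 with 16 bins and 2 trials.

## Known limitations

* The adaptive velocity threshold assumes a clear bimodal velocity
  distribution; very small saccades (< ~0.5 deg) fall below it by design.
* The trend-line smoother is a centered moving average; the trend of a
  series with long gaps is undefined inside those gaps, so the two-pass
  filter cannot flag outliers there (they are handled by the gap rules).
* PCA windows assume temporally localized variance clusters; overlapping
  slow processes would produce rotated components without clean windows,
  and `define_windows()` will error if a component owns no time points.
* The growth-curve LMM treats bin counts as continuous (scaled), which is
  adequate for 15-sample bins but not for very sparse bins.
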