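---
title: "Methods: pupil preprocessing, onset latency, and phase statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupil preprocessing, onset latency, and phase statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilphase)
```

## The analysis problem

Task-evoked pupil dilation in humans has (at least) two components: a fast
transient that begins ~0.6 s after movement onset and peaks about 0.9 s
later, attributed to relaxation of the parasympathetically driven iris
sphincter, and a sustained elevation that persists for as long as the
movement does, attributed to the sympathetically driven iris dilator.
Pharmacological designs dissociate them by instilling a mydriatic drop in
one eye (tropicamide to block the sphincter, phenylephrine to saturate the
dilator) and comparing evoked dilation between the treated and untreated
eye across trials of several durations. `pupilphase` implements the full
measurement chain such studies need, plus a generator that produces
synthetic datasets with known ground truth under the same design: 14
participants, 250 Hz binocular area recordings, sessions of 30 trials (10
each of 3, 6, 9 s), inter-trial intervals uniform on 5–8 s.

Everything configurable lives in `pupil_config()`; every default is the
value used in the analyses above (20 ms smoothing, 500 ms blink pairing,
−40/+80 ms masking, −1/+1 s epochs, 0.1 s baseline, 0.5–1.48 s early
phase, 25/75% latency fractions, α = 0.05), and a defaults unit test pins
them.

## Preprocessing

**Conversion.** Trackers report pupil *area*; diameter is
`sqrt(area * 4 / pi)`, applied element-wise, with missingness carried as a
mask (never a sentinel value). The tracker's native unit is not assumed:
`area_unit_scale` converts device units to mm² and defaults to 1 (i.e.
"already mm²") rather than guessing a device calibration.

**Smoothing.** Centered moving average over `smooth_window` (20 ms = 5
samples at 250 Hz), computing the mean of non-missing samples in the
window; a sample whose entire window is missing stays missing. At the
recording boundaries the window shrinks to the available samples — this
biases at most `(w-1)/2` edge samples, which never enter an epoch in
practice because trials start several seconds into a recording.

**Blink detection.** A blink is a pair of rapid decrease and rapid
increase within 500 ms. "Rapid" needed a concrete rule; we use the first
difference of the smoothed diameter expressed as velocity (mm/s) and flag
samples beyond ±k·σ̂ᵥ, with σ̂ᵥ the median-absolute-deviation scale
(×1.4826) of velocity over the whole recording and k = 5. MAD is used
precisely because blink transients themselves would inflate a plain SD.
Two numerical guards matter:

* σ̂ᵥ is floored by `blink_vel_floor` (25 mm/s). On a noise-free
  recording σ̂ᵥ is ~0, and without the floor the slow evoked ramp
  (≈0.4 mm/s) would be flagged; real blink edges exceed 100 mm/s, so the
  floor separates the two regimes by more than two orders of magnitude.
* A run of decrease candidates opens a blink; it closes at the end of the
  first increase run starting within the 500 ms pairing window, clamped to
  the window. A decrease that never pairs is still an artifact, so it is
  masked for the full pairing window and reported with `paired = FALSE`.

Masks are padded −40 ms/+80 ms, merged when overlapping, and masking is
monotone (it only adds missing samples). Blink *interpolation* is
deliberately out of scope: values stay missing.

## Epochs and averaging

Epochs run from 1 s before cue onset to 1 s after cue offset. The onset is
snapped to the nearest sample so all epochs share an exact 1/fs grid
(alignment bias ≤ 2 ms at 250 Hz, below the one-sample tolerance used for
latency validation). The baseline is the mean of non-missing samples in
[−0.1, 0) s; an epoch whose baseline window is fully missing is flagged
unusable, and an epoch extending past the recording is flagged truncated —
both are kept for reporting but excluded from averages. No further
trial-exclusion heuristics (e.g. variance-based rejection, or rejection of
epochs with heavy blink loss) are applied: only the two defined flags.

Condition averages are pointwise means over non-missing values. When
durations are pooled, the average at time *t* uses every epoch whose span
covers *t*, so `n(t)` steps down as shorter trials drop out. Grand
averages across participants are means of participant-level averages, not
trial-pooled means, matching the convention that each participant
contributes one trace to the statistics.

## Onset latency by 25/75% extrapolation

With the peak value *P* of the baseline-corrected mean trace inside the
search window, the estimator finds the first up-crossings of 0.25·*P* and
0.75·*P* before the peak (linear interpolation between samples) and
extrapolates the chord through those points to zero; the intersection is
the latency. Decisions behind the edges of that definition:

* **"Peak"** means the *initial* dilation peak, not the global maximum of
  a long trial; the search window defaults to [0, 3] s post-cue — the
  shortest trial length — which captures the initial peak while excluding
  late sustained drift. It is configurable (`latency_search`).
* **Crossings** are the first up-crossings scanned forward from the window
  start. If the trace already exceeds the lower threshold at the window
  start, no crossing exists and the estimate *fails* rather than guessing.
* **"No apparent increase"**: participants without a detectable rise must
  be excluded by an explicit rule; we fail the estimate when the peak is
  non-positive or below `latency_min_peak_sd` (3) standard deviations of
  the pre-cue baseline segment. This is the package's documented stand-in
  for an exclusion criterion that the emulated studies do not state.
* Latency is estimated per participant and eye on the across-trial mean
  trace; per-trial estimation is possible via the same function but is far
  noisier.

The estimator is exactly time-shift equivariant and amplitude invariant,
and on any trace whose rise is linear between the two crossings the chord
lies on the rise, so the extrapolation returns the true onset to within
one sample. Under additive noise of 10% of peak (after the pipeline's
20 ms smoothing) the median absolute error stays below 50 ms — both
properties are regression-tested.

## Phase statistics

Phase means are time-means over half-open windows on the sample grid:
early = [0.5, 1.48) s (onset-to-initial-peak of the fast component), late
= [1.48, duration) s, clipped to the trial.

**Within-subject ANOVA.** `rm_anova()` computes the full balanced
repeated-measures decomposition by inclusion–exclusion over marginal
totals; each effect is tested against its own subject-by-effect
interaction stratum. Incomplete or unbalanced tables are rejected with the
offending cells named — no silent imputation. Degenerate tables (zero
effect and zero error variance) report F = 0, p = 1 rather than 0/0. No
sphericity correction is applied by default, because the emulated analyses
report uncorrected df; Greenhouse–Geisser ε (computed from the effect's
contrast-space covariance) is available with `gg = TRUE`. The
implementation is validated against base R's `aov(y ~ . + Error(s/.))`
strata as an independent oracle, plus a sum-of-squares conservation
property on 1,000 random tables.

**Pooled-error simple main effects.** The characteristic df patterns of
this literature — F(1, 104) for an eye contrast in a 2×2×4 design with
n = 14, F(1, 26) for eye-within-phase in a 2×2×3 design — arise only when
the error term pools several subject-interaction strata. The rule
implemented: testing factor *f* with factors *B* fixed pools the strata of
every effect *E* with *f* ∈ *E* ⊆ {*f*} ∪ *B*; factors neither tested nor
fixed are averaged out, with totals kept on the full-data scale so the
simple-effect SS decompose exactly (Σ_b SS(f at b) = SS_f + SS_{f:B}).
Cell-wise error terms are available via `pooled = FALSE`.

**Ryan's procedure.** The "Ryan test" label covers several variants; we
implement the sequentially rejective version with nominal levels
α′(r) = 2α/(k(r−1)) for a comparison spanning r ordered means, tested from
the widest span inward, a pair being declared significant only if p <
α′(r) *and* every enclosing comparison was significant. With k = 2 this is
a plain t test at α. Raw two-sided p values are reported next to the
nominal levels; levels are adjusted, p values are not. This is our
documented interpretation, consistent with the t and p values such studies
print, not a claim about any specific prior implementation.

One printed statistic in the motivating literature (an F(3, 39) = 43.31
reported with p = 0.03) is internally inconsistent — that F at those df
implies p ≪ 0.001 — and is treated as a typo; only the df structure is
design-determined and reproduced.

## The synthetic-data generator

`simulate_study()` generates area-level datasets under the full design.
Per eye, diameter is baseline + fast(t) + slow(t) + hippus + noise, then
converted to area (so the pipeline's conversion is always exercised),
blink-collapsed, and noise-corrupted.

* **Fast component**: rises *linearly* from its onset latency (0.6 s) to
  its amplitude (0.35 mm) at onset + 0.88 s (initial peak at 1.48 s), then
  relaxes exponentially toward a 0.5 plateau fraction (τ = 0.8 s). The
  linear rise is a deliberate design choice: the 25/75% chord of a linear
  rise extrapolates exactly to the true onset, which gives the latency
  validation an exact ground truth; a saturating-exponential rise would
  make the estimand itself differ from the generator parameter by tens of
  milliseconds and turn every latency test into a test of that bias.
* **Sustained component**: saturating exponential (amplitude 0.30 mm,
  τ = 1.5 s) starting at 1.48 s — after the early window, so presets that
  only scale it leave the early phase untouched by construction. Both
  components decay with τ = 1 s after trial offset.
* **Drug presets** act on the treated eye: tropicamide-like halves the
  fast amplitude, delays it by 0.35 s, halves the sustained amplitude,
  baseline 7.0 mm; phenylephrine-like removes the sustained component,
  baseline 6.4 mm; control leaves the eyes exchangeable. Baselines
  (4.5–4.7 mm untreated, 6.4/7.0 mm treated) are typical session means for
  these drugs.
* **Artifacts**: binocular blinks as sharp multiplicative area collapses
  (×0.02) with Poisson rate 0.15/s, 80–180 ms duration and a 0.6 s
  minimum gap; hippus as a 0.2 Hz sinusoid of 0.03 mm; sensor noise as
  additive Gaussian area noise (SD 0.3 mm², ≈0.04 mm at a 5 mm pupil).
* **Between-participant variability**: log-normal amplitude factors
  (CV 0.15), normal onset-latency jitter (SD 0.08 s) and baseline jitter
  (SD 0.3 mm), drawn once per participant/eye; reaction times
  N(0.56, 0.09²) s truncated at zero.

Waveform, blink, noise and jitter magnitudes beyond the design constants
are the generator's own calibration, chosen once to produce realistic
traces (they are not measurements), and the manifest records every drawn
value so recovery tests key off ground truth rather than re-simulation.
The defaults ship as a versioned table
(`inst/extdata/sim-defaults-v1.conf`).

What the generator does **not** emulate: pharmacokinetic onset of the
drugs, the pupillary light reflex, gaze-dependent foreshortening, partial
occlusions or saccadic artifacts, and non-stationary noise. Passing the
validation suite therefore shows the pipeline is correct for data with
this structure; it does not certify behaviour under artifact classes the
generator never produces.

## Validation problem sizes

The heavy end-to-end checks run at deliberately chosen sizes: blink
recall/precision on 100 single-session-per-duration recordings; latency
noise calibration on 100 replicates; sum-of-squares conservation on 1,000
random tables; and the pharmacological recovery experiment on 100 seeded
replicates of 14 participants × 1 session × 30 trials (the single-session
design keeps each replicate self-contained; effect sizes, noise and
design constants stay at their defaults). The acceptance script's
headline run uses the full 14 × 3-session design.

## Known limitations

* The rm-ANOVA requires complete balanced data; missing cells must be
  handled upstream (the pipeline flags, reports and excludes unusable
  epochs but will refuse a participant missing an entire cell).
* Between-subject factors and mixed models are out of scope.
* The blink detector targets full-occlusion blinks; slow partial droops
  will not trigger the velocity rule.
* Latency estimation assumes the trace rises through both thresholds
  before the initial peak; traces already elevated at cue onset fail
  explicitly rather than extrapolating from a partial chord.
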