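---
title: "Models and methods behind lickwise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lickwise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickwise)
```

lickwise implements the analysis stack used to validate an optical
beam-break lickometer and to characterise licking microstructure in freely
moving mice, together with the fiber-photometry processing needed to align
a dopamine-sensor signal to licking. Because raw validation recordings of
this kind are rarely deposited, the package ships a first-class synthetic
module that generates ground-truth sessions with the statistical structure
the analyses assume; every downstream stage is tested against that known
truth.

## The behavioural task model

A reward (nominally 5 µl of sweetened solution) becomes available after an
intertrial interval (ITI) drawn from an exponential distribution with mean
18 s, *limited to* the interval [2, 30] s, and is delivered at the first
lick of the first lick bout that starts at or after the availability time.
Sessions last 30 min by default.

Two modelling choices here were genuinely open:

* **Truncation semantics.** "Limited to [2, 30]" can mean clamping draws to
  the bounds or conditioning the distribution on the interval. We condition
  (sampling by inversion of the truncated CDF, which has the same law as
  rejection sampling but a deterministic draw count): clamping would pile
  probability mass at exactly 2 s and 30 s, which is not how behavioural
  schedules are run. The conditional mean is
  `a + 1/λ − Δ e^{−λΔ}/(1 − e^{−λΔ})` ≈ 12.51 s for mean 18 s on [2, 30] s,
  and the sampler is tested against this closed form and against the
  analytic CDF (Kolmogorov–Smirnov at α = 0.01).
* **The ITI clock.** We anchor each ITI at the previous reward; bouts that
  start while the reward is still unavailable go unrewarded and do not
  reset the clock. Whether the 18 s refers to the pre- or post-truncation
  mean is ambiguous; we take it as the pre-truncation (exponential) mean
  and report the resulting conditional mean explicitly.

## The synthetic lick train

Licking in rodents is organised in bouts with a stereotyped within-bout
rhythm. The generator draws bout onsets from a homogeneous Poisson process
(default 0.05 bouts/s) with a hard refractory gap (0.55 s) appended after
the previous bout's last lick, bout sizes from a shifted geometric
distribution (mean 15 licks), and within-bout interlick intervals (ILIs)
from a truncated normal centred at 0.146 s with sd 0.015 s — the modal ILI
and its spread reported for this style of lickometer, which sits slightly
above classical contact lickometers because the recessed sipper lengthens
the tongue trajectory. Each lick is independently "short" (fails to reach
the sipper) with probability 27/230, the observed fraction.

Distributional choices the data do not pin down, made once:

* The ILI distribution is truncated on *both* sides (floor 0.05 s, ceiling
  0.45 s). The floor is the physiological minimum used by the artifact
  filter; the ceiling (just under the 0.5 s bout-break threshold) makes the
  generated bout labels and analysis-side bout segmentation agree exactly,
  so round-trip tests can demand exact label recovery. The ceiling clips
  about 10⁻²³ of the distribution's mass — it is a formal guarantee, not a
  material change.
* Lick durations are truncated normal (mean 60 ms, sd 20 ms) on
  [0.02, 0.2] s. The upper bound is the artifact filter's duration cutoff,
  so a clean true lick is never removed by construction. The lower bound is
  20 ms rather than the filter's 3 ms floor: a protrusion shorter than one
  60 Hz video frame (16.7 ms) cannot be validated against video at all,
  and real tongue contacts below 20 ms are marginal; with this bound every
  simulated lick is guaranteed at least one video frame, which the
  validation tests rely on. Durations are additionally capped 40 ms short
  of the next lick's onset so lick intervals never overlap.

## The sensor error model

The beam sits at sipper depth, so the simulated beam-break event occupies
the central half of each detected lick interval (the tongue crosses the
beam mid-protrusion). Corruption has three independent processes, with
defaults calibrated to the validation study's observed rates:

* **Misses by kind**: short licks are dropped with probability 10/27,
  sipper licks with 4/203 — the observed false-negative fractions. The
  resulting overall recall is 1 − (27/230 · 10/27 + 203/230 · 4/203) ≈ 94%.
* **Double detections** (beam flutter within one protrusion): probability
  0.05 per detected lick, onset 5–45 ms after the true event — always
  inside the filter's sub-50 ms ILI rejection zone.
* **Snout artifacts** (beam broken during exploration): a Poisson process
  at 0.048 events/s with lognormal durations (median 0.3 s, most mass above
  the 0.2 s duration cutoff, a minority below it so that some artifacts
  survive filtering, as observed). Artifacts are placed in lick-free time
  with a 0.25 s buffer from any lick and from each other, keeping
  false-positive provenance unambiguous for scoring tests.

Together these defaults give pre-filter precision near 89.5% and recall
near 94% on a default session, the operating point the device validation
reported. Post-filter precision rises to ~98% on synthetic data (the paper
analogue rose to 94%); the filter-effect tests assert only the qualitative
claim — precision strictly increases, recall is untouched — since absolute
post-filter precision depends on artifact composition that undeposited
data cannot constrain.

## Video scoring and matching

The study scored licks manually frame by frame; lickwise operationalises
that with thresholds. A video lick is a maximal run of frames with
tracking likelihood ≥ 0.9 and tongue displacement beyond the poke line
(tolerating one dropped frame), padded by one frame period per side to
compensate frame-sampling quantisation of the true protrusion interval;
its kind is "sipper" iff peak displacement reaches the sipper line. The
synthetic pose generator (60 Hz, trapezoidal excursions with 10% ramps)
round-trips through this segmentation exactly — every simulated lick is
recovered with its kind.

Matching uses a single unambiguous rule: an event belongs to the video
lick whose interval contains its *onset*. First event per lick → true
positive; later events in the same lick, or events in no lick → false
positives; unmatched licks → false negatives. Precision and recall are
reported both pooled and as mean ± SEM of per-session ratios (validation
studies report per-animal means; the two differ under imbalance, and both
are exposed).

The enrichment of misses among short licks is tested with a two-sided
Fisher's exact test, implemented by summing hypergeometric probabilities
no larger than the observed table's (with the customary 1 + 1e-7 relative
tie tolerance) and verified in the test suite against full enumeration
over every 2×2 table with N ≤ 40, and against `stats::fisher.test`.

## The post hoc artifact filter

True licks have durations in [3, 200] ms and never follow another lick
within 50 ms. The filter keeps an event iff its duration is inside the
window AND its onset-to-onset ILI against the previous *kept* event
exceeds 50 ms (first event passes vacuously). Two details are deliberate:

* The "duration ... and/or ILI" phrasing of such inclusion criteria is
  ambiguous; conjunctive keep-criteria are the default, and the
  disjunctive reading is available behind `rule = "either"`.
* Measuring the ILI against the previous kept event means a removed double
  detection cannot shield a subsequent double.

## Lick microstructure

ILIs are onset-to-onset by convention (offset-to-onset pauses are behind a
flag). Bouts are a greedy partition at a 0.5 s break threshold — the value
is not stated by the validation study but is implied by its treatment of
ILIs below 0.5 s as within-bout; it is exposed in the configuration. The
modal ILI is the centre of the maximal 10 ms histogram bin below the 0.5 s
ceiling (ties toward the smaller ILI); a fixed-width histogram rather than
a kernel density estimate keeps the "peak of the distribution" exactly
reproducible, at the cost of tying the estimate to the 10 ms bin width.
The primary ILI is the mean ILI inside the closed [0.05, 0.25] s window.
Cross-session consistency uses Pearson correlation with the standard t
transform for its p-value (delegated to `stats::cor.test`).

## Fiber photometry

The processing chain mirrors standard dLight practice: each channel
(470 nm signal, 415 nm isosbestic, 50 Hz) is detrended by subtracting a
robust LOWESS fit (fraction 0.1, 3 robustifying iterations, delta 20); the
detrended isosbestic is subtracted from the detrended signal; the result
is z-scored over the whole session with the population (divide-by-n)
standard deviation. Per-session rather than per-trial normalisation is the
default because no baseline window is specified for this kind of
recording; an optional per-trial baseline window exists in the PETH step.

The LOWESS smoother is written to the classic recipe: per point, a
weighted linear fit over the `ceiling(frac·n)` nearest samples with
tricube weights; robustness passes reweight by the bisquare of residuals
scaled by 6·median|r| (when that scale collapses to numerical zero the
pass is skipped, as reweighting would be ill-defined). `delta` is
interpreted in sample-index units (20 samples = 0.4 s at 50 Hz): exact
fits are computed at anchors at most delta apart and intermediate points
are linearly interpolated. Two properties matter for validation: with
`delta = 0` the fit equals a naive O(n²) reference to machine precision,
and the accelerated fit equals that reference exactly at its anchors with
chord interpolation in between. The interpolation itself deviates from
the exact fit by up to ~10⁻³–10⁻² near sharp transients (that deviation
is what the acceleration trades for its ~delta-fold speedup), so exact
oracle equivalence is asserted on the un-accelerated path, and the
accelerated path is pinned at anchors.

PETHs are extracted at nearest-sample alignment over a −1.5 s to +3.0 s
window — 226 timepoints at 50 Hz, the count implied by the
repeated-measures time degrees of freedom (225) reported for this design;
events without a full window are dropped and counted. Simulated reward
transients use a `(1 − e^{−t/0.05})·e^{−t/0.2}` kernel rescaled so its
sample-grid maximum equals the configured amplitude (1 a.u.; dips at
unrewarded first licks use the same shape scaled by −0.5), which makes
amplitude-recovery tests sharp: reading the PETH at the kernel's peak lag
recovers the amplitude to within three analytic standard errors after the
full detrend–subtract–align chain.

The rewarded/unrewarded comparison is a classical two-way within-subject
ANOVA computed from sums of squares on one mean trace per subject and
condition, each factor tested against its factor-by-subject interaction
(time and interaction on (T−1, (T−1)(n−1)) df, trial type on (1, n−1));
it is verified against `stats::aov` error strata to 10⁻⁸. The post hoc
significance mask uses per-timepoint paired t tests with Šidák correction
across timepoints by default (Bonferroni and uncorrected are available) —
the exact family behind shaded significance windows in published figures
is typically unstated, so the choice is exposed.

## Problem sizes and determinism

All randomness flows through R's global RNG: fixing a seed fixes every
output bit for bit, and `run_pipeline()` derives per-stage sub-seeds from
a single seed. The shipped tests and the acceptance script use sizes
chosen to estimate each quantity stably: 10⁶ draws for the ITI law,
200 half-hour sessions for the modal ILI (bias well under one histogram
bin), 30 000 s of licking (≥ 2000 short licks) for error-rate recovery,
100 seeded sessions for the filter-effect property, and 100 five-minute
photometry sessions (22 of which double as the subjects of the
repeated-measures design check) for transient and dip recovery.

## What the synthetic data does not capture

The generator emulates the statistical skeleton the analyses assume —
bout structure, kind-dependent misses, double/snout artifacts, bleaching,
shared artifacts, event-locked kernels — not the physics of a real rig.
Real pose estimates have correlated, heteroscedastic errors rather than
clean likelihood dips; real artifact durations and rates drift within
sessions; real dopamine kernels vary across events and animals; and real
false positives are more heterogeneous than the two processes modelled
here. Passing the recovery tests therefore demonstrates that the
estimators are correct and well-calibrated under the stated model, not
that the model exhausts real data. Headline numbers from the original
animal recordings (precision 89.5 ± 3.61%, recall 94.0 ± 2.42%, modal ILI
0.146 ± 0.015 s, the session correlations) are used as generator
calibration and qualitative targets only.
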