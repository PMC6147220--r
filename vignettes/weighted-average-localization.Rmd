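---
title: "Level-weighted averaging of synchronous sounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-weighted averaging of synchronous sounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waloc)
```

`waloc` is a pipeline for a classic question in spatial hearing: can the
auditory system segregate two synchronous broadband sounds in elevation,
where localization rests entirely on pinna-induced spectral-shape cues? The
package covers stimulus synthesis, factorial trial design, behavioral
simulation, head-saccade detection, and Bayesian model fitting. This
vignette documents the models, the tunable parameters, and the design
choices made where the problem left the design genuinely open.

## The localization model

Single-sound head-orienting responses are modeled as a linear function of
target elevation \(T\) (degrees, double-pole convention, positive up):

\[ R_s \sim \mathrm{Normal}(g\,T + b,\ \sigma_s) \]

with gain \(g\) (ideal 1), bias \(b\) in degrees (ideal 0), and response SD
\(\sigma_s\). For double sounds — an amplitude-modulated (AM) target at
\(T\) and a flat Gaussian-noise (GWN) distractor at \(D\) — the
weighted-average (WA) model predicts

\[ R_d \sim \mathrm{Normal}\big(g\,(w\,T + (1-w)\,D) + b,\ \sigma_d\big) \]

where \(w \in [0,1]\) is the target-location weight: \(w=0\) means the
response tracks only the distractor, \(w=0.5\) pure averaging, \(w=1\)
perfect segregation. At \(w=1\) the double-sound prediction reduces exactly
to the single-sound one — `wa_predict()` and `single_predict()` are
machine-identical there, which the tests assert.

One joint model per subject is fitted: \(g\), \(b\), \(\sigma_s\) are shared
across all trials (single and double trials are interleaved within a
session, so a subject's gain and bias cannot differ between them), while
\(w\) and \(\sigma_d\) get one value per (modulation frequency ΔL-level)
condition. A strict per-condition ablation — refitting \(g, b\) within one
cell — is obtained by calling `fit_localization()` on the subset of trials
of that cell; nothing in the implementation assumes the full grid except
`weight_curves(require_full_grid = TRUE)`.

Two-alternative forced-choice (up/down) discrimination data are binomial,
\(K \sim \mathrm{Binomial}(\theta, N)\), with a uniform Beta prior on the
correct-identification rate \(\theta\). The posterior is the exact conjugate
\(\mathrm{Beta}(K+1,\ N-K+1)\); an MCMC path exists purely to cross-check
the conjugate result.

## Priors

* \(b \sim \mathrm{Normal}(0°, 10°)\) and \(g \sim \mathrm{Normal}(1, 10)\):
  centered on ideal localization, essentially flat over the range observed
  in normal-hearing listeners.
* \(w \sim \mathrm{Beta}(1, 1)\): uniform, enforcing the unit-interval
  support without shaping.
* \(\sigma_s, \sigma_d \sim \mathrm{Gamma}(\text{shape}=1,\
  \text{rate}=0.04)\), i.e. mean 25° and effectively flat over 0–50°. The
  hyperparameters are a package choice (only "a Gamma prior" is determined
  by the problem); the test suite verifies that halving or doubling both
  hyperparameters moves the posterior mean of \(w\) by less than 0.02 at
  the per-cell trial counts of the full design, so nothing downstream
  depends on the exact values.

## The sampler

Sampling is Metropolis-within-Gibbs, exploiting the model's structure
rather than relying on tuning:

* \(g\) and \(b\) have exact normal full conditionals (normal prior, normal
  likelihood, linear mean).
* Each \(w_c\) has a normal likelihood in \(w\); under the uniform prior its
  full conditional is an exact truncated normal on \([0,1]\), sampled by
  inverse-CDF with an exponential-tilt fallback when the untruncated mass
  on the interval underflows. If a condition's trials all have \(T = D\),
  the conditional reduces to the prior — \(w\) is unidentifiable there and
  the posterior correctly returns Beta(1, 1), which is tested.
* The SDs have non-conjugate conditionals (Gamma prior on \(\sigma\)
  itself); they are updated by univariate slice sampling on
  \(\log\sigma\), which needs no step-size tuning. A floor of
  \(10^{-6}\) keeps the conditional proper in the degenerate case of
  exactly zero residuals.

Chains start from independent prior draws and differ only by seed. The
defaults follow the standard layout (3 chains of 10 000 samples, first
5 000 discarded); convergence is summarized by the Gelman-Rubin
\(\hat R\) (in-package implementation, cross-checked against `coda`), with
the conventional 1.1 bound. Because the \(g, b, w\) updates are exact Gibbs
draws, mixing is fast: \(\hat R\) at full scale is typically below 1.001.
Correctness of the sampler is defined by its target density and checked
three ways: prior recovery with zero data (Kolmogorov–Smirnov), the
conjugate Beta case for \(\theta\), and an independent JAGS fit of the same
model on the same data.

## Decision criteria

Summaries use 95% highest-density intervals — the shortest contiguous
interval holding 95% of the sorted draws (`hdi()`, validated against a
density-grid oracle and `coda::HPDinterval`'s convention). Group-level
summaries pool posterior *samples* across subjects (`pool_posteriors()`),
not parameters: there is no hierarchical partial pooling, by design.

Null-hypothesis tests use the Savage-Dickey density ratio: for the chance
null \(\theta = 0.5\) nested in the alternative,
\(\mathrm{BF}_{10} = p(0.5)/p(0.5 \mid y)\) (prior over posterior density).
For the conjugate Beta case this is analytic and matches brute-force
marginal-likelihood integration to better than \(10^{-6}\) relative error;
for sample-based posteriors the density at the null is estimated by a
Gaussian KDE with Silverman bandwidth. The KDE route is validated against
the analytic case, but it cannot estimate far-tail densities: when the
posterior lies far from the null the sample-based BF is reported as
infinite with a warning, while the analytic route remains exact. Evidence
labels follow the conventional 3/10/30/100 thresholds (substantial,
strong, very strong, decisive).

## Stimuli

Stimuli are band-limited (0.5–20 kHz) Gaussian noises at 48 828.125 Hz.
Numerical choices:

* **Band-pass filter**: a zero-phase frequency-domain brick-wall mask.
  Zero phase means the modulation envelope's timing is not skewed, and the
  stopband rejection is unbounded (the ≥ 40 dB requirement is met
  trivially); the DC bin is removed so waveforms are exactly zero-mean.
* **Envelope convention**: \(e(t) = 1 - d\cos(2\pi f_m t + \phi)\) with
  depth \(d\). At \(\phi = 0\) the stimulus starts at the envelope
  *minimum* (silence at 100% depth) and builds up. This convention is
  forced by the phenomenon the package models: a 5 Hz AM sound at phase 0
  must be initially softer than a level-equalized flat noise for the
  observed distractor bias — and its +3 dB shift of the 5 Hz weight curve —
  to arise. AM-carrier and GWN noise templates of a trial always use
  distinct seeds, so the two sounds are uncorrelated.
* **Level handling**: "dBA" is treated as dB RMS relative to a software
  reference; A-weighting and absolute SPL belong to playback hardware and
  are out of scope. `apply_am()` renormalizes to the input's full-duration
  RMS, mirroring per-stimulus physical level calibration. For a 5 Hz,
  150 ms stimulus (0.75 modulation period) the full-duration window is
  retained deliberately: the phase-dependent residual it leaves is a
  property of the physical stimulus, not an artifact.
* **Ramps**: sine-squared onset and cosine-squared offset, default 5 ms
  (the duration is configurable; 5 ms is a conventional click-suppression
  choice).
* **Initial-power analysis**: `windowed_power_difference()` compares an
  AM stimulus with a GWN over the first tens of milliseconds —
  the integration window the auditory system needs to extract elevation
  cues (~40–80 ms). `phase_power_profile()` sweeps the modulation phase,
  comparing each AM stimulus against its own level-equalized unmodulated
  carrier, which isolates the envelope effect from noise-template
  variability and makes the zero-depth case exactly 0 dB. Note that over a
  finite 50 ms window the profile's minimum is *not* at phase 0 but near
  \(7\pi/4\), where the envelope minimum falls mid-window: the profile
  tracks the windowed envelope-squared integral
  \(\int_0^W e(t)^2 dt\), and the tests verify it against that closed
  form.

## Trial designs

The three factorial designs reproduce the standard counts exactly: 720
double + 119 single = 839 localization trials; 120 double + 60 single
frequency-discrimination trials; 480 phase-discrimination trials (160
single + 320 double). Where the published design leaves details open, the
package fixes them as follows:

* **Speaker pairs**: the 24 double-sound elevation configurations are not
  enumerated publicly, only their ranges (elevations −45° to +75°,
  separations 15°–75°). The package constructs them once — two interleaved
  15°-spaced lattices offset by 5° on the cardinal-axis grid, separations
  tiling {15, 30, 45, 60, 75}° as 5/5/5/5/4 pairs — and freezes them as a
  versioned config file (`extdata/double_sound_pairs.csv`). The 17
  single-sound locations are exactly the unique elevations of those pairs
  (7 sound kinds × 17 locations = 119 single trials).
* **Levels**: each double trial draws its (AM, GWN) level pair uniformly
  from the calibrated {45…65} dBA grid pairs consistent with its ΔL.
* **Phase-experiment "sound types"**: the 2-level factor that doubles the
  phase design's double-sound count is read as which stimulus class
  occupies the upper speaker (AM-up/GWN-down vs GWN-up/AM-down), recorded
  in the `variant` column.
* Session structure (4 recording sessions) and fixation-timing jitter are
  metadata only and do not affect analysis.

## The synthetic-data generator

`default_behavior_params()` encodes the study conditions the simulation
emulates: weights following a logistic in ΔL (scale 2.2 dB) from ~0 at
−10 dB to ~1 at +10 dB; the 5 Hz curve shifted +3 dB (equal weighting
needs a 3 dB louder target, matching the initial-softness mechanism); gain
0.86 and single-sound SD 9° (mid-range of normal-hearing values, 0.82–0.90
and 8.2–10.9°); double-sound SD elevated (~11°) and peaking (~14°) at the
equal-weight point; identification near ceiling (0.98) for single targets,
0.5 for equal-level doubles at 120/2000 Hz, and 0.32 at 5 Hz with a
cosine phase dependence (0.28–0.48).

A rival **bistable** generator draws each double-sound response around the
target with probability `p_target`, else around the distractor, at
single-sound accuracy. The published record gives no quantitative bistable
model; this parametrization is the package's construction for
model-contrast testing. Its signature — which the tests formalize — is a
bimodal endpoint distribution whose residual spread around the WA
prediction strictly exceeds that of matched WA data, so a WA fit to
bistable data inflates \(\sigma_d\): increased variance at equal levels
cannot be mimicked by probabilistic averaging.

Head-orientation traces are synthesized at 6 kHz over 1500 ms:
minimum-jerk position profiles (single-peaked, symmetric velocity —
detection thresholds are specified by the problem, kinematics are not, and
minimum jerk is the standard smooth-movement model), movement duration
80 ms + 4 ms/deg of amplitude, plus low-pass (20 Hz) sensor noise of
0.02° SD, the resolution scale of a search-coil system behind its 120 Hz
acquisition filter. Reaction times are truncated-normal (250 ± 50 ms,
floor 160 ms) so default data pass the quality cut; the floor is
configurable to produce violations for testing.

What the generator does *not* emulate: acoustic propagation and
pinna filtering (responses are drawn directly from the behavioral model,
not from acoustics), azimuth behavior (fixed near 0), eye movements,
learning or sequential effects, and any cognitive process by which the
weight might arise from the stimulus. Passing tests therefore validate the
*pipeline* — designs, detection, inference, reporting — under the stated
behavioral models, not the models' truth for real listeners.

## Saccade detection

Velocity is the vectorial speed over azimuth and elevation after zero-phase
4th-order Butterworth smoothing at 40 Hz (balancing the 6 kHz sensor noise
floor against head-saccade dynamics; edge-replication padding suppresses
filter end transients). Onset and offset are the first upward and next
downward crossings of the 10°/s threshold after stimulus onset; crossings
must be sustained ≥ 10 ms to count, which rejects momentary noise
excursions. The endpoint estimator — not defined by the problem, since
listeners simply hold the end position — is the mean orientation over
100 ms starting 50 ms after offset. "Anomalous profile" is operationalized
as more than one velocity peak above threshold, counting distinct
above-threshold episodes plus within-episode local maxima separated by a
valley below half the lower peak (manual inspection cannot be reproduced;
the prominence rule keeps smooth profiles with noise ripples intact while
flagging genuine two-step movements). Quality control then discards null
responses, anomalous profiles, and reaction times below 150 ms (inclusive
boundary: exactly 150 ms is kept). `head_still_check()` for discrimination
trials uses a 5° excursion limit (inclusive), configurable.

End-to-end, synthetic saccades are recovered within 1° and 20 ms across
endpoints spanning −45° to +75°; the ~10 ms systematic onset delay is the
time a minimum-jerk velocity profile needs to reach 10°/s.

## Problem sizes and reproducibility

Every stochastic function takes a seed, and every derived seed stays below
\(2^{31}\). The test suite runs the full-scale fit (839 trials, 33
parameters, 3 × 10 000 samples) once for convergence, and calibrates
interval coverage with 200 replicate fits of a single condition cell at
per-cell scale (48 double + 17 single trials, 2 chains × 2000) — enough
replicates to make the 93–97% coverage band statistically meaningful.
Heavier Monte-Carlo settings (more replicates, longer chains) change
nothing qualitatively and can be run by adjusting the corresponding
arguments.

## Known limitations

* The KDE-based Savage-Dickey estimate degrades when the posterior is far
  from the null (reported as infinite with a warning); use the analytic
  route where conjugacy holds.
* `pool_posteriors()` concatenates samples; it is a descriptive group
  summary, not a hierarchical model.
* WAV export writes 32-bit float PCM with an integer-rounded sample-rate
  field (48 828 Hz in the header for the 48 828.125 Hz rate); the exact
  rate lives in the JSON sidecar.
* The bistable generator and its `p_target` parameter are a constructed
  rival, not an empirically fitted model.
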