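# waloc

Tools for studying how human listeners localize two *synchronous* broadband
sounds in the midsagittal plane, where only pinna-induced spectral-shape cues
carry elevation information. When an amplitude-modulated (AM) target noise and
a flat Gaussian-white-noise (GWN) distractor play simultaneously from
different elevations, listeners do not segregate them: head-orienting
responses point toward a **level-weighted average** of the two source
locations. `waloc` implements the complete computational pipeline around that
model: stimulus synthesis, factorial experiment designs, behavioral
simulation, head-saccade detection, and Bayesian inference.

## The model

For a double-sound trial with target elevation `T`, distractor elevation `D`,
response `R`:

    R ~ Normal(mu, sigma_d),   mu = g * (w * T + (1 - w) * D) + b

and for interleaved single-sound trials `R ~ Normal(g * T + b, sigma_s)`.
Here `g` is the localization gain (ideal 1), `b` the bias in degrees (ideal
0), and `w` in [0, 1] the target-location weight: 0 means the response
ignores the target, 0.5 means pure averaging, 1 means perfect segregation.
`g`, `b` and `sigma_s` are shared across all trials of a subject; `w` and
`sigma_d` vary per (modulation frequency, level difference) condition. The
weight rises with the AM-vs-GWN level difference ΔL: the averaging is
level-weighted.

Up/down two-alternative forced-choice data are modeled binomially,
`K ~ Binomial(theta, N)`, with a uniform prior on the correct-identification
rate `theta`; evidence against the chance null `theta = 0.5` is quantified by
the Savage-Dickey Bayes factor `BF10` (ratio of prior to posterior density at
0.5).

Inference is by MCMC (Metropolis-within-Gibbs; normal priors on `g` and `b`,
Gamma priors on SDs, uniform Beta on `w`), with 95% highest-density
intervals, Gelman-Rubin convergence diagnostics, and across-subject pooling
of posterior samples.

A second mechanism the package quantifies: a 5 Hz AM sound at modulation
phase 0 starts at its envelope minimum, so its power over the first ~50 ms —
the window the auditory system uses to extract elevation cues — is well below
that of a level-equalized flat noise. `phase_power_profile()` measures this
phase-dependent initial-level effect, which explains the distractor bias
observed for slow modulations.

## Worked example

Simulate one subject's full localization experiment (839 trials: 720 double
+ 119 single), fit the joint model, and summarize the 120 Hz weight curve:

```r
library(waloc)

trials    <- build_localization_trials(seed = 1)
responses <- simulate_localization(trials, default_behavior_params(), seed = 2)
post      <- fit_localization(trials, responses, n_chains = 3,
                              n_samples = 4000, n_burn = 2000, seed = 3)
wc <- weight_curves(post)
wc[wc$fm_hz == 120, c("delta_l_db", "w_mean", "w_sd", "sigma_d_mean")]
#> # A tibble: 5 × 4
#>   delta_l_db w_mean   w_sd sigma_d_mean
#>        <dbl>  <dbl>  <dbl>        <dbl>
#> 1        -10 0.0791 0.0393         12.5
#> 2         -5 0.107  0.0413         12.4
#> 3          0 0.589  0.0595         17.3
#> 4          5 0.893  0.0369         10.9
#> 5         10 0.970  0.0223         10.1
```

The recovered weights rise monotonically with the level difference — near 0
when the distractor is 10 dB louder, near 1 when the target is 10 dB louder,
and close to 0.5 averaging at equal level, where the response variability
`sigma_d` also peaks. That is the level-weighted-average signature the
generator embodies and the fit recovers.

Discrimination data use the conjugate Beta posterior. A listener scoring 30
correct out of 160 (systematically choosing the distractor side):

```r
fit_discrimination(K = 30, N = 160)
#> <discrimination: K=30/160, theta = 0.191 [0.132, 0.252], BF10 = 3.3e+13 (decisive)>
```

The identification rate is credibly below chance (95% HDI excludes 0.5) with
decisive evidence against `theta = 0.5`.

`run_pipeline()` chains design → simulation → fitting → reporting and writes
CSV summaries plus a seed manifest, so every artifact is regenerable.

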