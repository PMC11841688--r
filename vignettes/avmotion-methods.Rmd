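---
title: "Models and methods behind avmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind avmotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avmotion)
```

This vignette is the package's own account of the science it implements:
the generative observer, the psychometric models, the three cue-combination
models, the kinematics preprocessing, and — importantly — the numerical and
design choices made where the underlying methodology left the design open.
No empirical claim is made here that the test suite does not itself
compute.

## 1. The task and its coordinate-frame problem

An observer makes self-paced yaw head rotations while fixating a
head-fixed light, and judges whether an auditory, visual, or audio–visual
stimulus moved with or against the head. Stimulus velocity is *gain
coded*: a movement gain `g` means the stimulus moves at `g` times the
concurrent head speed (positive = with the head). The canonical design
crosses 8 conditions (audio / visual / audio–visual, each with or without
positional jitter on the applicable modalities) with 13 gains spanning
0 to ±0.5 and 30 repetitions: 3120 trials per observer.

Because vision starts eye-centered and hearing head-centered, each cue
must be compensated into body-centered coordinates with an internal
self-movement estimate before integration. The compensated cues share the
noise of that self-movement estimate — the package's central quantity,
`σ_SM`.

## 2. The generative observer

`simulate_trials()` draws, per trial, a head speed `h` from
`Normal(head_mu, head_sd²)` truncated below at `head_floor` (default
15 deg/s — stimuli vanish below that speed, so slower trials are never
judged; truncation is by rejection sampling). For each present modality
`m` the body-centered amplitude estimate is

```
D_m = (g − (1 − r_m))·h + ε_img,m + ε_SM
```

with `ε_img,m ~ N(0, σ_img,m²)` (a larger SD when the condition carries
positional jitter) and `ε_SM ~ N(0, σ_SM²)` drawn **once per trial and
shared** between modalities. Unimodal responses are `with` iff `D_m > 0`.
Audio–visual responses combine `D_av = w_a D_a + w_v D_v` with weights
from the correlation-adjusted reliabilities evaluated at the true total
noises (Section 4), so parameter recovery against the BCI+ model is exact
by construction; `av_rule = "bci"` switches to plain reliability weights
for model-discrimination experiments. With probability `lapse` the
response is replaced by a fair coin flip (a symmetric lapse, matching the
left/right symmetry of the task).

Choices worth making explicit:

* **Amplitude units.** All generative noises are in deg/s because the
  judgment is coded as motion *amplitude*, not motion gain. Dividing by
  the head speed yields the gain-unit psychometric parameters; a
  convenience constructor (`observer_params_gain()`) accepts gain units
  directly.
* **Bias mechanism.** The unimodal bias is produced entirely by the
  compensation gain `r_m` (PSE `= 1 − r_m`); the shared noise is
  zero-mean. How empirical biases decompose between under-compensation
  and image-speed misestimation is not identifiable from this task; this
  parameterization makes bias and shared noise independently controllable.
* **Defaults.** `head_mu = 80`, `head_sd = 10` deg/s are typical
  self-paced yaw sweep speeds for this paradigm; `σ_img` defaults
  (audio 14/20, visual 8/16 deg/s plain/jittered, `σ_SM = 6`) put the
  gain-unit SDs near 0.1–0.3 with the visual cue the more reliable one
  and jitter clearly inflating noise, and give `ρ ≈ 0.2–0.3`;
  `lapse = 0.01` sits in the middle of the fitted lapse box `[0, 0.02]`.
  These are the package's stated world: property tests run against them
  and they are not tuned per test.
* With `head_sd = 0` the psychometric function is an exact cumulative
  Gaussian and `analytic_psychometric()` provides the closed-form oracle
  (unimodal: PSE `1 − r_m`, SD `√(σ_img² + σ_SM²)/head_mu`).

The stimulus-side details are emulated by `generate_stimulus_trace()`
(world position = gain × head displacement, plus piecewise-constant jitter
uniform on ±7.5° redrawn at 5 Hz — "±7.5° wide" is read as half-width
7.5°, configurable) and `gate_stimulus_level()` (level halves per frame
below the speed threshold; it **resets to 1** when speed recovers — the
recovery rule of the original leaky integrator is unstated, and a reset is
the simplest behavior consistent with "decrease by 50% for each frame
spent below threshold"). The judged sweep is the third; simulated trial
records carry `sweep_index = 3` and a single signed median head velocity.

What the generator deliberately does **not** emulate: session structure
and fatigue, serial dependencies, eye-movement contamination of the
decision variable (fixation is assumed maintained), non-Gaussian image
noise, and any hardware latency. A green test therefore establishes that
the *analysis* is correct under the stated generative assumptions, not
that those assumptions describe any particular observer.

## 3. Psychometric models

`fit_cumulative_gaussian()` maximizes the binomial likelihood of

```
P(with | g) = λ + (1 − 2λ)·Φ((g − α)/σ),   λ ∈ [0, 0.02]
```

over `(α, log σ, λ)` with bounded quasi-Newton (L-BFGS-B) using an
analytic gradient, started at probit-regression values plus four jittered
restarts, followed by a Nelder–Mead polish. The polish exists because
L-BFGS-B line searches can abort on the numerically flat likelihood near
the optimum; the simplex step refines the solution and provides the
honest `converged` flag. Ties between starts are broken by higher
log-likelihood, then smaller `σ`. All-`with` or all-`against` data are
returned as a typed `psychfit_unidentifiable` outcome rather than a
silent failure. Degenerate gain levels with zero trials are dropped with
a warning.

`bootstrap_fit()` resamples Bernoulli outcomes **within each gain level**
at the empirical proportions and refits. Stratification by gain is the
only resampling scheme consistent with the fixed method-of-constant-
stimuli design. Non-converged replicates are dropped and counted; a
failure rate above 20% raises a warning carried in the result.

### The across-trial-noise model

Because judgments are amplitude-coded, trial-to-trial head-speed
variability injects noise that a standard psychometric fit misattributes:
at high head-speed variance the observed proportions approach asymptotes
shallower than 0/1 (beyond what a `λ ≤ 0.02` lapse can absorb) while the
central slope steepens. `fit_across_trial_model()` fits

```
P(with | g) = λ + (1 − 2λ)·E_h[Φ((g − g₀)·h/σ_amp)]
```

with the expectation over the floor-truncated Gaussian head-speed
distribution measured by `fit_velocity_distribution()` — measured, not
fitted. The expectation uses fixed-grid trapezoid quadrature with 129
nodes spanning `[max(floor, μ − 8sd), μ + 8sd]`; the acceptance suite
checks it against a 10⁶-draw Monte-Carlo oracle to 10⁻⁴. At
`head_sd = 0` the model reduces exactly to the standard fit with
`σ = σ_amp/μ`, which the tests verify to 1%. The truncation floor is the
same 15 deg/s the simulator uses.

## 4. The three cue-combination models

Each audio–visual condition is predicted from the two unimodal
*predicting conditions* with matching jitter flags (the `predicting_pairs()`
table): e.g. the visual-jitter AV condition is predicted from the jittered
visual and the plain audio condition.

**BCI** (body-centered integration) — standard maximum-likelihood cue
combination on the compensated cues: reliabilities `rel_m = 1/σ_m²`,
weights `w_m = rel_m/(rel_a + rel_v)`, predicted bias
`Ŝ_av = w_a Ŝ_a + w_v Ŝ_v`, predicted SD
`σ_av = √(σ_a²σ_v²/(σ_a² + σ_v²))`. The unimodal estimators need not be
unbiased for the precision prediction to hold.

**BCI+** — the same, adjusted for the correlation `ρ` the shared
self-movement noise induces:

```
ρ      = σ_SM²/(σ_a σ_v)
rel_a  = 1/σ_a² − ρ/(σ_a σ_v)        (and symmetrically rel_v)
rel_av = [1/σ_a² + 1/σ_v² − 2ρ/(σ_a σ_v)] / (1 − ρ²)
σ_av   = 1/√rel_av
```

`ρ` is **never a free parameter**: it is computed from the separately
measured `σ_SM²` via `compute_rho()`, which also enforces `0 ≤ ρ < 1`
(shared noise exceeding a cue's total noise is inconsistent and raises a
typed error). These are the standard correlated-cue combination forms; one
can verify directly that the adjusted-reliability weights are the
minimum-variance convex weights for two Gaussian cues with correlation
`ρ`, and that the generative observer of Section 2 realizes exactly this
combined variance. When `ρ` exceeds the cue-SD ratio one adjusted
reliability turns negative; a negative weight has no likelihood
interpretation here, so the offending reliability is clamped to zero
(complete capture by the other cue) and the result is flagged as a typed
`vetoed_cue` outcome carrying both raw reliabilities.

**ICI** (image-centered integration) — integration without compensation.
The variance sum law strips the self-movement variance from each unimodal
variance (`σ_m_Im² = σ_m² − σ_SM²`, `variance_sum_law()`), the BCI
precision formula is applied to the image noises, and — because image
cues are assumed internally consistent — the predicted bias is exactly 0.
`σ_SM²` at least as large as a unimodal variance is a typed
`negative image variance` error; inside `predict_all()` such a sample is
carried as an excluded row (`sigma_av = NA`) rather than a failure,
mirroring how negative self-movement variances are excluded upstream.

`estimate_sigma_sm()` pools up to three per-repetition `σ_SM²`
measurements: negative repetitions (possible when a sampled self-movement
precision exceeds the cue precisions) are excluded and the mean of the
remainder is used; all-negative input yields a typed
`shared_noise_excluded` outcome. The three-repetition measurement itself
is external to this package; `simulate_sm_repetitions()` provides a
generic simulated stand-in (matched condition pairs with and without
self-movement noise) so the full chain can be exercised end-to-end.

## 5. Kinematics preprocessing

* `lowpass_head()`: zero-phase FFT-domain filtering with a Butterworth
  *magnitude* response of order 10 — −3 dB at the 8 Hz passband, ≈60 dB
  one octave above, DC gain exactly 1, reflection padding of about one
  second against edge transients. The original analysis names only a
  proprietary lowpass routine with a passband; a zero-phase
  frequency-domain design meets the fixed constraints without inventing a
  time-domain topology.
* `detect_turn()`: causal 13-sample finite-difference smoothing of the
  derivative (mean slope over the trailing 12 intervals); a turn is the
  first sample whose smoothed derivative flips sign, which on a noise-free
  triangle wave lags the true reversal by exactly `(L+1)/2 = 7` samples
  (≈30 ms at 240 Hz).
* `segment_sweeps()`: noise-free reversal detection by sign change of the
  central-difference derivative, ties at zero derivative breaking toward
  the earlier sample. `median_sweep_velocity()` takes the median
  derivative over 20–60% of the judged sweep.
* `fit_velocity_distribution()`: maximum-likelihood Gaussian — sample
  mean and *population* (divide-by-n) variance; the convention matters
  for the two-point examples in the tests.
* `preprocess_eye()`: samples under 0.6 confidence are interpolated
  linearly; a waveform with ≤50% surviving samples is rejected as a typed
  outcome (the rejection is applied per waveform, i.e. per trial — the
  source is silent on per-trial vs per-session). Smoothing multiplies the
  spectrum by `exp(−f²/(2·16²))` (a 16 Hz frequency-domain Gaussian,
  equivalent to a time-domain Gaussian kernel of SD `1/(2π·16)` s ≈ 10 ms);
  velocity, acceleration, and jerk are central differences (one-sided at
  the edges) and 20 samples are trimmed at each end.
* `remove_saccades()`: the jerk threshold is treated as 20,000 deg/s³
  (the source prints the number with squared-second units while calling
  it jerk); detections are padded by 4 samples on each side.
* `expected_vor()`: `E = −H(1 + R/D)` with defaults `R = 0.1` m,
  `D = 1.2` m.

## 6. Evaluation

`squared_errors()` produces per-(condition, model) squared differences of
predicted vs fitted precision and bias, with ICI excluded from bias (its
prediction is identically zero by assumption, not by fit).
`bootstrap_difference_ci()` builds percentile CIs of replicate-wise
prediction-minus-empirical differences (replicates paired by index);
percentile rather than BCa because the reference analysis does not
specify the variant, and percentile is the simplest scheme consistent
with it. `model_rmse_table()` maps predicted parameters to implied
curves — through the across-trial model when head-speed distributions are
supplied — and scores RMSE against observed proportions. `rank_models()`
orders models by cohort mean error and counts strictly-best cases; ties
count for neither model. Repeated-measures ANOVA machinery is deliberately
out of scope; the exported long-format tables feed any standard
statistics environment.

## 7. Testing strategy, tolerances, and scaling

* Hand-derivable values (reliability arithmetic, VOR, variance sum law)
  are frozen into tests from independent arithmetic.
* Stochastic properties run under fixed seeds with bands stated up front:
  Monte-Carlo vs closed-form agreement within 3 binomial SEs; BCI+
  parameter recovery within 3 bootstrap SEs in ≥90% of
  replicate × condition × parameter checks; model discrimination ordering
  BCI+ ≤ BCI ≤ ICI in ≥80% of simulated cohorts.
* Heavy resampling is scaled to fit a CPU-minute budget and the scaling is
  stated where it happens: bootstrap SE bands use 200 resamples instead
  of the reference 2000 (the SE of a bootstrap SE at 200 resamples is
  ~5%, immaterial against a 3-SE band); the CI-coverage property uses 200
  replications. Thresholds and bands themselves are never rescaled.
* The coverage band (90–98% for 95% CIs) reflects that percentile
  bootstrap CIs on 30-trials-per-level binomial data undercover slightly;
  measured coverage in this package's stated world is ≈94% at 300
  resamples.

## 8. Known limitations

* The generative observer realizes one specific bias decomposition
  (compensation gain); real observers may mix mechanisms that this task
  cannot separate.
* The across-trial model here implements the described mechanism
  (amplitude-coded decisions marginalized over measured head-speed
  variability); it is this package's formulation, not a reproduction of
  any toolbox's internal code.
* `σ_SM` enters predictions as an external measurement; the package's
  three-repetition stand-in is synthetic and labeled as such.
* Percentile CIs and the stratified bootstrap are choices among defensible
  alternatives; both are isolated behind small functions if a BCa or
  trial-level resampling variant is ever needed.
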