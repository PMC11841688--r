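# Shared fixtures: small observers and fitting shortcuts used across files.

# default test observer with a fixed head speed (closed forms apply)
fixed_head_observer <- function(..., lapse = 0) {
  observer_params(head_sd = 0, lapse = lapse, ...)
}

# noiseless, perfectly compensated observer
noiseless_observer <- function(r_audio = 1, r_visual = 1, lapse = 0) {
  observer_params(sigma_img_audio = 1e-9, sigma_img_visual = 1e-9,
                  sigma_sm = 1e-9, r_audio = r_audio, r_visual = r_visual,
                  head_sd = 0, lapse = lapse)
}

# simulate one condition and fit the standard psychometric model
sim_and_fit <- function(params, cond, n_reps, seed, gains = gain_grid()) {
  trials <- simulate_trials(params, n_reps = n_reps, gains = gains,
                            conditions = cond, seed = seed)
  fit_cumulative_gaussian(bin_responses(trials))
}

# binned data drawn from an exact cumulative Gaussian
synthetic_binned <- function(alpha, sigma, lapse = 0, n_per = 100,
                             gains = gain_grid(), seed = NULL) {
  p <- lapse + (1 - 2 * lapse) * pnorm((gains - alpha) / sigma)
  draw <- function() binned_data(gains, rbinom(length(gains), n_per, p),
                                 rep(n_per, length(gains)))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
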