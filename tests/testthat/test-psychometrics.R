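# Binning, cumulative-Gaussian MLE, bootstrap, across-trial-noise model

test_that("binning counts responses per gain and guards its inputs", {
  tr <- data.frame(
    label = "a", gain = rep(0.1, 30),
    response = rep(c("with", "against"), c(12, 18)))
  b <- bin_responses(tr)
  expect_equal(b$n_with, 12)
  expect_equal(b$n_total, 30)

  # canonical slice: 13 rows of 30
  sched <- simulate_trials(fixed_head_observer(), n_reps = 30,
                           conditions = condition("audio"), seed = 21)
  b2 <- bin_responses(sched)
  expect_equal(nrow(b2), 13)
  expect_true(all(b2$n_total == 30))

  expect_error(bin_responses(tr[0, ]), class = "avmotion_validation_error")
  tr2 <- rbind(tr, data.frame(label = "v", gain = 0.1, response = "with"))
  expect_error(bin_responses(tr2), class = "avmotion_validation_error")
})

test_that("MLE recovers generating parameters at large n", {
  dat <- synthetic_binned(alpha = 0.05, sigma = 0.15, n_per = 1e4, seed = 31)
  fit <- fit_cumulative_gaussian(dat)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha - 0.05), 0.005)
  expect_lt(abs(fit$sigma - 0.15) / 0.15, 0.05)
})

test_that("symmetric data yield a PSE at zero", {
  g <- gain_grid()
  n <- rep(200L, length(g))
  k <- round(n * pnorm(g / 0.2))
  k <- pmax(pmin((k + rev(n - k)) / 2, n), 0)    # symmetrize exactly
  fit <- fit_cumulative_gaussian(binned_data(g, as.integer(k), n))
  expect_lt(abs(fit$alpha), 1e-4)
})

test_that("gain-shift equivariance holds", {
  dat <- synthetic_binned(alpha = 0.02, sigma = 0.12, n_per = 500, seed = 32)
  fit <- fit_cumulative_gaussian(dat)
  shifted <- binned_data(dat$gain + 0.1, dat$n_with, dat$n_total)
  fit2 <- fit_cumulative_gaussian(shifted)
  expect_equal(fit2$alpha, fit$alpha + 0.1, tolerance = 1e-4)
  expect_equal(fit2$sigma, fit$sigma, tolerance = 1e-4)
  expect_equal(fit2$lapse, fit$lapse, tolerance = 1e-4)
})

test_that("fitted likelihood dominates the generating parameters", {
  withr::with_seed(33, {
    for (i in 1:10) {
      alpha <- runif(1, -0.1, 0.1)
      sigma <- runif(1, 0.08, 0.3)
      lapse <- runif(1, 0, 0.02)
      dat <- synthetic_binned(alpha, sigma, lapse, n_per = 100)
      fit <- fit_cumulative_gaussian(dat)
      ll_true <- sum(dbinom(dat$n_with, dat$n_total,
                            pmin(pmax(lapse + (1 - 2 * lapse) *
                                        pnorm((dat$gain - alpha) / sigma),
                                      1e-12), 1 - 1e-12), log = TRUE))
      expect_gte(fit$loglik, ll_true - 1e-6)
    }
  })
})

test_that("all-identical responses are an unidentifiable typed outcome", {
  dat <- binned_data(gain_grid(), rep(30L, 13), rep(30L, 13))
  out <- fit_cumulative_gaussian(dat)
  expect_s3_class(out, "psychfit_unidentifiable")
  expect_true(out$all_with)
  expect_error(fit_cumulative_gaussian(binned_data(c(0, 0.1), c(1, 5),
                                                   c(10, 10))),
               class = "avmotion_validation_error")
})

test_that("bootstrap is seed-deterministic and tracks sampling noise", {
  dat <- synthetic_binned(alpha = 0.03, sigma = 0.15, n_per = 30, seed = 34)
  b1 <- bootstrap_fit(dat, n = 100, seed = 5)
  b2 <- bootstrap_fit(dat, n = 100, seed = 5)
  expect_identical(b1$samples, b2$samples)

  # degenerate step data at huge n: essentially no resampling variance
  g <- gain_grid()
  step <- binned_data(g, ifelse(g > 0, 10000L, 0L) + ifelse(g == 0, 5000L, 0L),
                      rep(10000L, 13))
  bs <- bootstrap_fit(step, n = 50, seed = 6)
  expect_lt(sd(bs$samples$alpha), 0.002)

  # bootstrap SE approximates the sampling SD over fresh datasets
  boot <- bootstrap_fit(dat, n = 400, seed = 7)
  fresh <- withr::with_seed(8, replicate(200, {
    fit_cumulative_gaussian(
      synthetic_binned(alpha = 0.03, sigma = 0.15, n_per = 30),
      n_restarts = 1, polish = FALSE)$alpha
  }))
  expect_lt(abs(sd(boot$samples$alpha) - sd(fresh)) / sd(fresh), 0.25)
})

test_that("bootstrap CIs cover the generating PSE at the nominal rate", {
  # scaled for runtime: 400 replications x 200 resamples (the reference
  # analysis uses 2000 resamples; measured coverage in this stated world is
  # ~93%, so 400 replications bound the sampling error of the check at ~1.3
  # percentage points); the 90-98% band itself is unchanged
  hits <- withr::with_seed(41, vapply(1:400, function(i) {
    dat <- synthetic_binned(alpha = 0.04, sigma = 0.15, lapse = 0.01,
                            n_per = 30)
    b <- bootstrap_fit(dat, n = 200)
    ci <- quantile(b$samples$alpha, c(0.025, 0.975), names = FALSE)
    ci[1] <= 0.04 && 0.04 <= ci[2]
  }, logical(1)))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.98)
})

test_that("across-trial model reduces to the standard fit at zero variance", {
  dat <- synthetic_binned(alpha = 0.05, sigma = 0.15, n_per = 200, seed = 35)
  std <- fit_cumulative_gaussian(dat)
  at <- fit_across_trial_model(dat, fit_velocity_distribution(c(80, 80)))
  expect_equal(at$g0, std$alpha, tolerance = 0.01 * max(abs(std$alpha), 0.01))
  expect_lt(abs(at$sigma_amp / 80 - std$sigma) / std$sigma, 0.01)
})

test_that("head-speed variability compresses standard-fit asymptotes", {
  # strongly variable head speeds: the amplitude-coded observer's asymptotes
  # deviate from 0/1 in gain coordinates
  p <- observer_params(head_mu = 60, head_sd = 30, lapse = 0)
  trials <- simulate_trials(p, n_reps = 150,
                            conditions = condition("audio"), seed = 36)
  dat <- bin_responses(trials)
  hd <- fit_velocity_distribution(abs(trials$head_velocity))
  std <- fit_cumulative_gaussian(dat)
  at <- fit_across_trial_model(dat, hd)
  expect_gt(at$loglik, std$loglik)
  # the standard fit needs its lapse pinned at the bound to mimic the
  # compressed asymptotes
  expect_gt(std$lapse, 0.015)
})

test_that("quadrature matches a Monte-Carlo expectation closely", {
  hd <- list(mean = 80, variance = 225)
  gains <- c(-0.2, -0.05, 0.08, 0.3)
  quad <- across_trial_curve(gains, g0 = 0.02, sigma_amp = 12, hd)
  mc <- withr::with_seed(37, {
    h <- rnorm(2e5, hd$mean, sqrt(hd$variance))
    h <- h[h >= 15]
    vapply(gains, function(g)
      mean(pnorm((g - 0.02) * h / 12)), numeric(1))
  })
  expect_equal(quad, mc, tolerance = 0.002)
})

test_that("model-implied curves behave and match simulation", {
  fit <- structure(list(alpha = 0.04, sigma = 0.12, lapse = 0),
                   class = "psychfit")
  expect_equal(model_implied_curve(fit, 0.04), 0.5)
  curve <- model_implied_curve(fit, seq(-0.5, 0.5, 0.05))
  expect_true(all(diff(curve) > 0))

  # large simulation agrees with the implied curve
  p <- fixed_head_observer(lapse = 0)
  an <- analytic_psychometric(p, condition("audio"))
  gains <- c(-0.2, 0, 0.2)
  trials <- simulate_trials(p, n_reps = 5e4, gains = gains,
                            conditions = condition("audio"), seed = 38)
  dat <- bin_responses(trials)
  implied <- pnorm((gains - an$pse) / an$sigma)
  expect_true(all(abs(dat$n_with / dat$n_total - implied) < 0.005))
})

test_that("rmse is the root mean squared difference", {
  expect_equal(rmse(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(rmse(c(0, 1), c(1, 0)), 1)
  expect_equal(rmse(c(0.4, 0.6), c(0.5, 0.5)), 0.1)
  expect_equal(rmse(rep(0.3, 5), rep(0.25, 5)), 0.05)
  expect_error(rmse(1:3, 1:2), class = "avmotion_validation_error")
})
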