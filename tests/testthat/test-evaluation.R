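# Squared-error tables, difference CIs, RMSE tables, rankings, report I/O

fake_predictions <- function() {
  est <- list(
    a = unimodal_estimate("audio", 0.02, 0.18),
    a_aj = unimodal_estimate("audio", 0.03, 0.28, jitter = TRUE),
    v = unimodal_estimate("visual", 0.10, 0.12),
    v_vj = unimodal_estimate("visual", 0.12, 0.22, jitter = TRUE))
  predict_all(est, shared_noise(0.004))
}

test_that("squared errors are zero at equality and (pred-emp)^2 otherwise", {
  preds <- fake_predictions()
  emp <- lapply(split(preds, preds$condition), function(s) {
    list(alpha = s$pse_av[s$model == "BCI"], sigma = s$sigma_av[s$model == "BCI"])
  })
  tab <- squared_errors(preds, emp, participant_id = "p1")
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$sq_err_precision[tab$model == "BCI"] == 0))
  expect_true(all(tab$sq_err_bias[tab$model == "BCI"] == 0))
  # ICI is excluded from bias comparisons: 4 x 2 usable bias rows
  expect_true(all(is.na(tab$sq_err_bias[tab$model == "ICI"])))
  expect_equal(sum(!is.na(tab$sq_err_bias)), 8)

  emp2 <- lapply(emp, function(e) list(alpha = e$alpha, sigma = e$sigma + 0.02))
  tab2 <- squared_errors(preds, emp2)
  expect_equal(tab2$sq_err_precision[tab2$model == "BCI"],
               rep(4e-4, 4), tolerance = 1e-12)
  expect_error(squared_errors(preds, emp[-1]),
               class = "avmotion_validation_error")
})

test_that("difference CIs classify zero containment correctly", {
  x <- withr::with_seed(51, rnorm(500, 0, 0.01))
  same <- bootstrap_difference_ci(x, x)
  expect_equal(c(same$lower, same$upper), c(0, 0))
  expect_true(same$contains_zero)

  shifted <- bootstrap_difference_ci(x + 0.05, x)
  expect_false(shifted$contains_zero)
  expect_equal(shifted$lower, 0.05, tolerance = 1e-9)

  expect_warning(bootstrap_difference_ci(x[1:50], x[1:50] + rnorm(50, 0, 1e-3)),
                 regexp = "fewer than 100")
})

test_that("model RMSE table compares implied curves to observed proportions", {
  preds <- fake_predictions()
  g <- gain_grid()
  # observed proportions exactly on the BCI curve of each condition
  av_data <- lapply(split(preds, preds$condition), function(s) {
    pr <- pnorm((g - s$pse_av[s$model == "BCI"]) / s$sigma_av[s$model == "BCI"])
    binned_data(g, round(pr * 1e6), rep(1e6, 13))
  })
  tab <- model_rmse_table(av_data, preds)
  expect_true(all(tab$rmse[tab$model == "BCI"] < 1e-3))
  expect_true(all(tab$rmse[tab$model == "ICI"] >
                    tab$rmse[tab$model == "BCI"]))
  expect_error(model_rmse_table(av_data[-1], preds),
               class = "avmotion_validation_error")
})

test_that("rank_models orders by cohort mean and counts strict wins", {
  tab <- data.frame(
    participant_id = rep(c("p1", "p2"), each = 3),
    condition = "av",
    model = rep(c("BCI+", "BCI", "ICI"), 2),
    err = c(0.0017, 0.002, 0.003, 0.0017, 0.002, 0.003))
  rk <- rank_models(tab, "err")
  expect_equal(rk$ranking$model, c("BCI+", "BCI", "ICI"))
  expect_equal(rk$best_counts$n_best[rk$best_counts$model == "BCI+"], 2)
  expect_equal(unique(rk$best_counts$n_cases), 2)

  one <- rank_models(tab[tab$model == "BCI", ], "err")
  expect_equal(one$ranking$model, "BCI")

  tied <- tab
  tied$err[tied$model == "BCI"] <- 0.0017
  rk2 <- rank_models(tied, "err")
  expect_true(any(rk2$ranking$tied))
  # ties count for neither model
  expect_equal(sum(rk2$best_counts$n_best), 0)
})

test_that("cohort tables are permutation-invariant to participant order", {
  preds <- fake_predictions()
  emp <- lapply(split(preds, preds$condition), function(s)
    list(alpha = 0.05, sigma = 0.1))
  t1 <- squared_errors(preds, emp, "p1")
  t2 <- squared_errors(preds, emp, "p2")
  t2$sq_err_precision <- t2$sq_err_precision * 2
  a <- cohort_error_table(list(t1, t2))
  b <- cohort_error_table(list(t2, t1))
  expect_equal(a, b)
})

test_that("report bundle round-trips and is byte-identical across runs", {
  tab <- data.frame(condition = "av", model = "BCI", rmse = 0.08)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- list(n_reps = 2, seed = 9)
  report(list(rmse_table = tab), d1, config = cfg, seed = 9)
  report(list(rmse_table = tab), d2, config = cfg, seed = 9)
  back <- read.csv(file.path(d1, "rmse_table.csv"))
  expect_equal(back$rmse, tab$rmse)
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
})

test_that("prediction CIs propagate unimodal bootstrap uncertainty", {
  # simulated observer whose generative AV rule is BCI+: its CI should
  # contain zero for both parameters on a well-behaved seed
  p <- fixed_head_observer(lapse = 0)
  trials <- simulate_trials(p, n_reps = 30, seed = 53)
  fits <- fit_participant(trials, boot_n = 150, seed = 53)
  shared <- (p$sigma_sm / p$head_mu)^2
  cis <- bootstrap_prediction_cis(fits, shared)
  expect_equal(nrow(cis), 4 * (3 * 2 - 1))       # ICI has no bias row
  expect_true(all(cis$lower <= cis$upper))
  expect_true(all(cis$contains_zero == (cis$lower <= 0 & cis$upper >= 0)))
  bciplus <- cis[cis$model == "BCI+" & cis$condition == "av", ]
  expect_true(all(bciplus$contains_zero))
  expect_error(bootstrap_prediction_cis(fit_participant(trials), shared),
               class = "avmotion_validation_error")
})

test_that("with no shared noise, BCI and BCI+ errors are indistinguishable", {
  # generator without self-movement noise: rho = 0, the two models coincide
  p <- fixed_head_observer(sigma_sm = 0, lapse = 0)
  trials <- simulate_trials(p, n_reps = 30, seed = 52)
  res <- analyze_participant(trials, shared_noise(0))
  err <- res$errors
  d <- err$sq_err_precision[err$model == "BCI"] -
       err$sq_err_precision[err$model == "BCI+"]
  expect_true(all(abs(d) < 1e-10))
})
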