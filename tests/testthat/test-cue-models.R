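# BCI, BCI+, ICI model algebra, shared-noise estimation, Table-2 pairing

ue <- function(modality, pse, sigma, jitter = FALSE)
  unimodal_estimate(modality, pse = pse, sigma = sigma, jitter = jitter)

test_that("BCI matches hand-worked reliability arithmetic", {
  # symmetric cues: midpoint bias, sigma/sqrt(2)
  p1 <- bci_predict(ue("audio", 0, 0.2), ue("visual", 0.1, 0.2))
  expect_equal(p1$pse_av, 0.05)
  expect_equal(p1$sigma_av, 0.2 / sqrt(2))

  # unequal cues: w_a = 0.2, w_v = 0.8
  p2 <- bci_predict(ue("audio", 0.02, 0.2), ue("visual", 0.10, 0.1))
  expect_equal(p2$w_a, 0.2)
  expect_equal(p2$w_v, 0.8)
  expect_equal(p2$pse_av, 0.084)
  expect_equal(p2$sigma_av, sqrt(0.008))

  # infinite-reliability limit
  p3 <- bci_predict(ue("audio", 0.02, 0.2), ue("visual", 0.10, 1e-6))
  expect_equal(p3$pse_av, 0.10, tolerance = 1e-6)
  expect_lt(p3$sigma_av, 1e-5)

  expect_error(bci_predict(ue("audio", 0, 0.2), list(pse = 0, sigma = -1)),
               class = "avmotion_validation_error")
})

test_that("rho is the shared-to-product noise ratio with a validity box", {
  expect_equal(compute_rho(0, 0.2, 0.1), 0)
  expect_equal(compute_rho(0.01, 0.2, 0.1), 0.5)
  expect_equal(compute_rho(shared_noise(0.01), 0.2, 0.1), 0.5)
  expect_error(compute_rho(0.03, 0.2, 0.1),
               class = "avmotion_inconsistent_shared_noise")
})

test_that("BCI+ reduces to BCI at rho = 0 and obeys its closed forms", {
  a <- ue("audio", 0.02, 0.2)
  v <- ue("visual", 0.10, 0.1)
  p0 <- bci_plus_predict(a, v, 0)
  ref <- bci_predict(a, v)
  expect_identical(p0$pse_av, ref$pse_av)
  expect_equal(p0$sigma_av, ref$sigma_av, tolerance = 1e-15)

  # equal variances: sigma_av = sigma * sqrt((1 + rho)/2), bias midpoint
  for (rho in c(0.1, 0.4, 0.8)) {
    pe <- bci_plus_predict(ue("audio", 0.0, 0.15), ue("visual", 0.1, 0.15),
                           rho)
    expect_equal(pe$sigma_av, 0.15 * sqrt((1 + rho) / 2), tolerance = 1e-12)
    expect_equal(pe$pse_av, 0.05, tolerance = 1e-12)
  }

  # hand-worked boundary case: adjusted audio reliability exactly 0
  ph <- bci_plus_predict(a, v, 0.5)
  expect_equal(ph$w_a, 0)
  expect_equal(ph$pse_av, 0.10)
  expect_equal(ph$sigma_av, 0.1)

  # beyond the boundary: vetoed cue, raw reliabilities carried
  pv <- bci_plus_predict(a, v, 0.7)
  expect_s3_class(pv, "vetoed_cue")
  expect_lt(pv$rel_a_raw, 0)
  expect_equal(pv$w_a, 0)

  expect_error(bci_plus_predict(a, v, 1),
               class = "avmotion_validation_error")
})

test_that("shared-noise penalty grows with rho for equal variances", {
  rhos <- seq(0, 0.95, 0.05)
  sig <- vapply(rhos, function(r)
    bci_plus_predict(ue("audio", 0, 0.15), ue("visual", 0, 0.15), r)$sigma_av,
    numeric(1))
  expect_true(all(diff(sig) > 0))
  expect_equal(sig[1], 0.15 / sqrt(2))
})

test_that("fusion benefit and bias convexity hold over random draws", {
  withr::with_seed(14, {
    sa <- runif(500, 0.02, 0.5)
    sv <- runif(500, 0.02, 0.5)
    pa <- runif(500, -0.3, 0.3)
    pv <- runif(500, -0.3, 0.3)
    rho <- runif(500, 0, 0.95)
    for (i in 1:500) {
      b <- bci_predict(ue("audio", pa[i], sa[i]), ue("visual", pv[i], sv[i]))
      expect_lte(b$sigma_av, min(sa[i], sv[i]))
      expect_gte(b$pse_av, min(pa[i], pv[i]))
      expect_lte(b$pse_av, max(pa[i], pv[i]))
      bp <- bci_plus_predict(ue("audio", pa[i], sa[i]),
                             ue("visual", pv[i], sv[i]), rho[i])
      if (!inherits(bp, "vetoed_cue")) {
        expect_gte(bp$pse_av, min(pa[i], pv[i]) - 1e-12)
        expect_lte(bp$pse_av, max(pa[i], pv[i]) + 1e-12)
      }
    }
  })
})

test_that("variance sum law and repetition pooling follow the exclusion rule", {
  expect_equal(variance_sum_law(0.04, 0.04), 0)
  expect_equal(variance_sum_law(0.05, 0.01), 0.04)
  expect_equal(variance_sum_law(0.01, 0.05), -0.04)
  expect_error(variance_sum_law(-0.1, 0), class = "avmotion_validation_error")

  s1 <- estimate_sigma_sm(c(0.004, 0.006, 0.005))
  expect_equal(s1$sigma_sm_sq, 0.005)
  expect_equal(s1$reps_used, 3L)
  s2 <- estimate_sigma_sm(c(0.004, -0.002, 0.005))
  expect_equal(s2$sigma_sm_sq, 0.0045)
  expect_equal(s2$reps_used, 2L)
  expect_equal(s2$reps_excluded, 1L)
  s3 <- estimate_sigma_sm(c(-0.001, -0.002, -0.003))
  expect_s3_class(s3, "shared_noise_excluded")
  expect_error(estimate_sigma_sm(numeric(0)),
               class = "avmotion_validation_error")
})

test_that("ICI strips shared noise and predicts zero bias, always", {
  a <- ue("audio", 0.02, 0.2)
  v <- ue("visual", 0.10, 0.1)
  # degenerate: no shared noise -> same sigma as BCI, but zero bias
  p0 <- ici_predict(a, v, shared_noise(0))
  expect_equal(p0$sigma_av, bci_predict(a, v)$sigma_av)
  expect_identical(p0$pse_av, 0)

  # hand-worked: sigma_sm^2 = 0.0036
  p1 <- ici_predict(a, v, shared_noise(0.0036))
  expect_equal(p1$sigma_av, sqrt(0.0364 * 0.0064 / 0.0428), tolerance = 1e-12)
  expect_identical(p1$pse_av, 0)

  expect_error(ici_predict(a, v, shared_noise(0.02)),
               class = "avmotion_negative_image_variance")

  withr::with_seed(15, {
    for (i in 1:50) {
      sa <- runif(1, 0.1, 0.5); sv <- runif(1, 0.1, 0.5)
      ssq <- runif(1, 0, 0.9 * min(sa, sv)^2)
      expect_identical(
        ici_predict(ue("audio", runif(1), sa), ue("visual", runif(1), sv),
                    shared_noise(ssq))$pse_av, 0)
    }
  })
})

test_that("predict_all enforces the predicting-condition pairing", {
  est <- list(
    a = ue("audio", 0.02, 0.18),
    a_aj = ue("audio", 0.03, 0.28, jitter = TRUE),
    v = ue("visual", 0.10, 0.12),
    v_vj = ue("visual", 0.12, 0.22, jitter = TRUE))
  out <- predict_all(est, shared_noise(0.004))
  expect_equal(nrow(out), 12)                   # 4 AV conditions x 3 models
  expect_setequal(unique(out$model), c("BCI", "BCI+", "ICI"))

  # visual-jitter AV condition pairs jittered visual with plain audio
  pairs <- predicting_pairs()
  row <- pairs[pairs$visual_jitter & !pairs$audio_jitter, ]
  expect_equal(row$visual_pred_label, "v_vj")
  expect_equal(row$audio_pred_label, "a")
  # and its BCI prediction is built from exactly those sigmas
  bci_row <- out[out$condition == row$av_label & out$model == "BCI", ]
  ref <- bci_predict(est$a, est$v_vj)
  expect_equal(bci_row$sigma_av, ref$sigma_av)

  # swapped-pair injection is rejected
  bad <- est
  bad$v_vj <- ue("visual", 0.12, 0.22, jitter = FALSE)
  expect_error(predict_all(bad, shared_noise(0.004)),
               class = "avmotion_validation_error")
  expect_error(predict_all(est[-1], shared_noise(0.004)),
               regexp = "missing predicting condition")
})
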