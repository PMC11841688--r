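#' Unimodal psychometric estimate for a predicting condition
#'
#' Bundles the fitted PSE (bias, gain units) and SD (inverse precision, gain
#' units) of one unimodal condition, optionally with bootstrap replicates of
#' the two parameters for confidence-interval propagation.
#'
#' @param modality `"audio"` or `"visual"`.
#' @param pse Point of subjective equality, gain units.
#' @param sigma SD of the fitted cumulative Gaussian, gain units; must be > 0.
#' @param jitter Whether the condition carried positional jitter.
#' @param boot Optional data frame / matrix with columns `pse`, `sigma` of
#'   bootstrap replicates.
#' @return An object of class `unimodal_estimate`.
#' @export
unimodal_estimate <- function(modality = c("audio", "visual"), pse, sigma,
                              jitter = FALSE, boot = NULL) {
  modality <- match.arg(modality)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_validation("sigma must be a single positive number")
  if (!is.null(boot)) {
    boot <- as.data.frame(boot)
    stopifnot(all(c("pse", "sigma") %in% names(boot)))
  }
  structure(
    list(modality = modality, jitter = isTRUE(jitter),
         pse = as.numeric(pse), sigma = as.numeric(sigma), boot = boot),
    class = "unimodal_estimate"
  )
}

new_prediction <- function(model, pse_av, sigma_av, w_a, w_v, rho = NA_real_,
                           extra = NULL, subclass = NULL) {
  structure(
    c(list(model = model, pse_av = pse_av, sigma_av = sigma_av,
           w_a = w_a, w_v = w_v, rho = rho), extra),
    class = c(subclass, "cue_prediction")
  )
}

#' @export
print.cue_prediction <- function(x, ...) {
  cat(sprintf("%s prediction: PSE = %.4f, sigma = %.4f (w_a = %.3f, w_v = %.3f%s)\n",
              x$model, x$pse_av, x$sigma_av, x$w_a, x$w_v,
              if (is.na(x$rho)) "" else sprintf(", rho = %.3f", x$rho)))
  if (inherits(x, "vetoed_cue"))
    cat("  note: one adjusted reliability was negative and was clamped to 0\n")
  invisible(x)
}

check_sigmas <- function(sigma_a, sigma_v) {
  if (any(!is.finite(c(sigma_a, sigma_v))) || any(c(sigma_a, sigma_v) <= 0))
    stop_validation("cue SDs must be finite and > 0")
}

#' Body-centered integration (BCI) prediction
#'
#' Standard maximum-likelihood cue combination on compensated (body-centered)
#' cues. Reliabilities are inverse variances, weights are normalized
#' reliabilities, the predicted audio-visual bias is the reliability-weighted
#' sum of the unimodal biases, and the predicted SD is
#' `sqrt(sigma_a^2 sigma_v^2 / (sigma_a^2 + sigma_v^2))`.
#'
#' @param a,v `unimodal_estimate` objects (audio, visual), or plain lists with
#'   `pse` and `sigma` fields.
#' @return A `cue_prediction` with model tag `"BCI"`.
#' @export
#' @examples
#' a <- unimodal_estimate("audio", pse = 0.02, sigma = 0.2)
#' v <- unimodal_estimate("visual", pse = 0.10, sigma = 0.1)
#' bci_predict(a, v)
bci_predict <- function(a, v) {
  check_sigmas(a$sigma, v$sigma)
  rel_a <- 1 / a$sigma^2
  rel_v <- 1 / v$sigma^2
  w_a <- rel_a / (rel_a + rel_v)
  w_v <- rel_v / (rel_a + rel_v)
  sigma_av <- sqrt(a$sigma^2 * v$sigma^2 / (a$sigma^2 + v$sigma^2))
  new_prediction("BCI", w_a * a$pse + w_v * v$pse, sigma_av, w_a, w_v)
}

#' Cue correlation induced by shared self-movement noise
#'
#' The correlation between the compensated auditory and visual cues is the
#' ratio of the shared self-movement variance to the product of the total
#' cue SDs: `rho = sigma_sm^2 / (sigma_a * sigma_v)`. A valid correlation
#' requires `0 <= rho < 1`; shared noise exceeding either cue's total noise
#' is inconsistent and raises a typed error.
#'
#' @param shared A [shared_noise()] object, or a single nonnegative number
#'   taken as `sigma_sm^2` in gain-units squared.
#' @param sigma_a,sigma_v Total unimodal SDs, gain units.
#' @return The correlation `rho` (scalar in `[0, 1)`).
#' @export
#' @examples
#' compute_rho(0.01, sigma_a = 0.2, sigma_v = 0.1) # 0.5
compute_rho <- function(shared, sigma_a, sigma_v) {
  check_sigmas(sigma_a, sigma_v)
  ssq <- if (inherits(shared, "shared_noise")) shared$sigma_sm_sq else shared
  if (!is.numeric(ssq) || length(ssq) != 1L || ssq < 0)
    stop_validation("sigma_sm^2 must be a single nonnegative number")
  rho <- ssq / (sigma_a * sigma_v)
  if (rho >= 1)
    stop(errorCondition(
      sprintf("inconsistent shared noise: rho = %.4g >= 1 (shared noise cannot exceed either cue's total noise)", rho),
      class = c("avmotion_inconsistent_shared_noise", "avmotion_error")))
  rho
}

#' Body-centered integration adjusted for shared noise (BCI+)
#'
#' Optimal combination of two correlated cues. The correlation `rho` deflates
#' each cue's effective reliability
#' (`rel_a = 1/sigma_a^2 - rho/(sigma_a sigma_v)`, and symmetrically for the
#' visual cue); weights are the normalized adjusted reliabilities; the
#' combined reliability is
#' `rel_av = (1/sigma_a^2 + 1/sigma_v^2 - 2 rho/(sigma_a sigma_v)) / (1 - rho^2)`
#' and the predicted SD is `1/sqrt(rel_av)`. With `rho = 0` this reduces
#' exactly to [bci_predict()].
#'
#' When one adjusted reliability is negative (possible when `rho` exceeds the
#' cue-SD ratio) the offending reliability is clamped to 0 — complete capture
#' by the other cue — and the result carries class `vetoed_cue` plus both raw
#' adjusted reliabilities.
#'
#' @inheritParams bci_predict
#' @param rho Cue correlation in `[0, 1)`, from [compute_rho()].
#' @return A `cue_prediction` with model tag `"BCI+"` (possibly subclass
#'   `vetoed_cue`).
#' @export
bci_plus_predict <- function(a, v, rho) {
  check_sigmas(a$sigma, v$sigma)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop_validation("rho must lie in [0, 1)")
  cross <- rho / (a$sigma * v$sigma)
  rel_a_raw <- 1 / a$sigma^2 - cross
  rel_v_raw <- 1 / v$sigma^2 - cross
  vetoed <- rel_a_raw < 0 || rel_v_raw < 0
  rel_a <- max(rel_a_raw, 0)
  rel_v <- max(rel_v_raw, 0)
  w_a <- rel_a / (rel_a + rel_v)
  w_v <- rel_v / (rel_a + rel_v)
  rel_av <- (1 / a$sigma^2 + 1 / v$sigma^2 - 2 * cross) / (1 - rho^2)
  new_prediction(
    "BCI+", w_a * a$pse + w_v * v$pse, 1 / sqrt(rel_av), w_a, w_v, rho,
    extra = if (vetoed) list(rel_a_raw = rel_a_raw, rel_v_raw = rel_v_raw),
    subclass = if (vetoed) "vetoed_cue"
  )
}

#' Variance sum law subtraction
#'
#' Subtracts one variance component from a total variance. The result may be
#' negative; policy is the caller's ([estimate_sigma_sm()] excludes negative
#' values, [ici_predict()] errors on them).
#'
#' @param sigma_total_sq,sigma_other_sq Nonnegative variances (gain units
#'   squared). Vectorized.
#' @return `sigma_total_sq - sigma_other_sq`.
#' @export
variance_sum_law <- function(sigma_total_sq, sigma_other_sq) {
  if (any(sigma_total_sq < 0) || any(sigma_other_sq < 0))
    stop_validation("variances must be >= 0")
  sigma_total_sq - sigma_other_sq
}

#' Shared self-movement variance estimate
#'
#' Combines up to three per-repetition estimates of the self-movement
#' variance (each a [variance_sum_law()] subtraction, which can come out
#' negative when a repetition's sampled self-movement precision exceeds the
#' cue precisions). Negative repetitions are excluded and the estimate is the
#' mean of the remainder; when all repetitions are negative the estimate is
#' excluded entirely (a typed outcome, not an error).
#'
#' @param rep_estimates Numeric vector of 1-3 per-repetition `sigma_sm^2`
#'   values, gain units squared.
#' @return An object of class `shared_noise` with fields `sigma_sm_sq`,
#'   `reps_used`, `reps_excluded`; or class `shared_noise_excluded` when all
#'   repetitions were negative.
#' @export
#' @examples
#' estimate_sigma_sm(c(0.004, -0.002, 0.005)) # mean of the two positives
estimate_sigma_sm <- function(rep_estimates) {
  if (length(rep_estimates) < 1L || length(rep_estimates) > 3L)
    stop_validation("between 1 and 3 repetition estimates are required")
  keep <- rep_estimates >= 0
  if (!any(keep)) {
    return(structure(
      list(sigma_sm_sq = NA_real_, reps_used = 0L,
           reps_excluded = length(rep_estimates)),
      class = c("shared_noise_excluded", "shared_noise")))
  }
  shared_noise(mean(rep_estimates[keep]),
               reps_used = sum(keep), reps_excluded = sum(!keep))
}

#' @rdname estimate_sigma_sm
#' @param sigma_sm_sq Self-movement variance, gain units squared.
#' @param reps_used,reps_excluded Repetition bookkeeping.
#' @export
shared_noise <- function(sigma_sm_sq, reps_used = 1L, reps_excluded = 0L) {
  if (!is.numeric(sigma_sm_sq) || length(sigma_sm_sq) != 1L || sigma_sm_sq < 0)
    stop_validation("sigma_sm_sq must be a single nonnegative number")
  structure(list(sigma_sm_sq = sigma_sm_sq,
                 reps_used = as.integer(reps_used),
                 reps_excluded = as.integer(reps_excluded)),
            class = "shared_noise")
}

#' Image-centered integration (ICI) prediction
#'
#' Integration of uncompensated image-motion cues: the self-movement variance
#' is stripped from each unimodal variance by the variance sum law
#' (`sigma_m_Im^2 = sigma_m^2 - sigma_sm^2`) and the BCI precision formula is
#' applied to the image noises. Because image cues are assumed unbiased, the
#' predicted audio-visual PSE is exactly 0.
#'
#' @inheritParams bci_predict
#' @param shared A [shared_noise()] object (or nonnegative scalar variance).
#' @return A `cue_prediction` with model tag `"ICI"` and `pse_av = 0`.
#' @export
ici_predict <- function(a, v, shared) {
  check_sigmas(a$sigma, v$sigma)
  ssq <- if (inherits(shared, "shared_noise")) shared$sigma_sm_sq else shared
  if (!is.numeric(ssq) || length(ssq) != 1L || is.na(ssq) || ssq < 0)
    stop_validation("sigma_sm^2 must be a single nonnegative number")
  va <- variance_sum_law(a$sigma^2, ssq)
  vv <- variance_sum_law(v$sigma^2, ssq)
  if (va <= 0 || vv <= 0)
    stop(errorCondition(
      "negative image variance: sigma_sm^2 >= a unimodal total variance",
      class = c("avmotion_negative_image_variance", "avmotion_error")))
  rel_a <- 1 / va
  rel_v <- 1 / vv
  new_prediction("ICI", 0, sqrt(va * vv / (va + vv)),
                 rel_a / (rel_a + rel_v), rel_v / (rel_a + rel_v))
}

#' Predicting-condition pairing for the audio-visual conditions
#'
#' Each audio-visual condition is predicted from the unimodal conditions with
#' the matching jitter flags: the visual predictor shares the AV condition's
#' visual-jitter flag and the audio predictor its audio-jitter flag.
#'
#' @return A 4-row data frame: `av_label`, `audio_jitter`, `visual_jitter`,
#'   `audio_pred_label`, `visual_pred_label`.
#' @export
predicting_pairs <- function() {
  av <- av_conditions()
  av <- av[av$modality == "audio_visual", ]
  data.frame(
    av_label = av$label,
    audio_jitter = av$audio_jitter,
    visual_jitter = av$visual_jitter,
    audio_pred_label = ifelse(av$audio_jitter, "a_aj", "a"),
    visual_pred_label = ifelse(av$visual_jitter, "v_vj", "v"),
    stringsAsFactors = FALSE
  )
}

#' All model predictions for the four audio-visual conditions
#'
#' Selects, for each audio-visual condition, the correct unimodal predicting
#' pair and produces the BCI, BCI+, and ICI predictions (12 in total).
#'
#' @param estimates Named list of `unimodal_estimate` objects keyed by
#'   condition label (`"a"`, `"a_aj"`, `"v"`, `"v_vj"`).
#' @param shared A [shared_noise()] object in gain units squared.
#' @return A data frame with one row per (AV condition, model):
#'   `condition`, `model`, `pse_av`, `sigma_av`, `w_a`, `w_v`, `rho`, a
#'   `vetoed` flag (BCI+ negative adjusted reliability), and an `excluded`
#'   flag (ICI shared noise exceeding a cue's total noise; `sigma_av` is
#'   then `NA`). Attribute `"predictions"` carries the underlying
#'   `cue_prediction` objects.
#' @export
predict_all <- function(estimates, shared) {
  pairs <- predicting_pairs()
  need <- unique(c(pairs$audio_pred_label, pairs$visual_pred_label))
  missing <- setdiff(need, names(estimates))
  if (length(missing))
    stop_validation(paste0("missing predicting condition(s): ",
                           paste(missing, collapse = ", ")))
  for (lbl in need) {
    est <- estimates[[lbl]]
    want_mod <- if (substr(lbl, 1, 1) == "a") "audio" else "visual"
    if (!identical(est$modality, want_mod))
      stop_validation(sprintf(
        "predicting condition '%s' must be %s (got %s)", lbl, want_mod,
        est$modality))
    want_jit <- grepl("j", lbl)
    if (!identical(isTRUE(est$jitter), want_jit))
      stop_validation(sprintf(
        "predicting condition '%s' has the wrong jitter flag", lbl))
  }
  rows <- list()
  preds <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- estimates[[pairs$audio_pred_label[i]]]
    v <- estimates[[pairs$visual_pred_label[i]]]
    rho <- compute_rho(shared, a$sigma, v$sigma)
    p <- list(
      BCI = bci_predict(a, v),
      `BCI+` = bci_plus_predict(a, v, rho),
      # a sample with shared noise exceeding a cue's total noise cannot be
      # used by the ICI model; carry the exclusion instead of failing
      ICI = tryCatch(ici_predict(a, v, shared),
                     avmotion_negative_image_variance = function(e)
                       new_prediction("ICI", 0, NA_real_, NA_real_,
                                      NA_real_, subclass = "excluded_sample"))
    )
    for (m in names(p)) {
      pr <- p[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = pairs$av_label[i], model = m,
        pse_av = pr$pse_av, sigma_av = pr$sigma_av,
        w_a = pr$w_a, w_v = pr$w_v, rho = pr$rho,
        vetoed = inherits(pr, "vetoed_cue"),
        excluded = inherits(pr, "excluded_sample"),
        stringsAsFactors = FALSE
      )
      preds[[paste(pairs$av_label[i], m, sep = ".")]] <- pr
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- preds
  out
}
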