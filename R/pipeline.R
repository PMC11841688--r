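#' Fit every condition of one participant's trial table
#'
#' Bins and fits the standard psychometric model per condition label,
#' optionally with a nonparametric bootstrap per condition.
#'
#' @param trials Trial table for one participant.
#' @param boot_n Bootstrap replicates per condition (0 = none).
#' @param seed Optional integer seed for the bootstraps.
#' @param lapse_max Lapse bound.
#' @return Named list of `psychfit` objects keyed by condition label, each
#'   with a `boot` element when `boot_n > 0`.
#' @export
fit_participant <- function(trials, boot_n = 0, seed = NULL,
                            lapse_max = 0.02) {
  labels <- unique(trials$label)
  fits <- list()
  for (i in seq_along(labels)) {
    dat <- bin_responses(trials[trials$label == labels[i], ])
    fit <- fit_cumulative_gaussian(dat, lapse_max = lapse_max)
    if (boot_n > 0 && inherits(fit, "psychfit"))
      fit$boot <- bootstrap_fit(dat, n = boot_n,
                                seed = if (is.null(seed)) NULL else seed + i,
                                lapse_max = lapse_max)
    fits[[labels[i]]] <- fit
  }
  fits
}

# unimodal estimates (for predict_all) from a fit list
unimodal_estimates_from_fits <- function(fits) {
  out <- list()
  for (lbl in intersect(c("a", "a_aj", "v", "v_vj"), names(fits))) {
    f <- fits[[lbl]]
    if (!inherits(f, "psychfit")) next
    out[[lbl]] <- unimodal_estimate(
      modality = if (substr(lbl, 1, 1) == "a") "audio" else "visual",
      pse = f$alpha, sigma = f$sigma, jitter = grepl("j", lbl),
      boot = if (!is.null(f$boot))
        data.frame(pse = f$boot$samples$alpha, sigma = f$boot$samples$sigma))
  }
  out
}

#' Simulated stand-in for the self-movement-precision repetitions
#'
#' The shared self-movement variance is measured, in the original paradigm,
#' in a separate three-repetition experiment and extracted by the variance
#' sum law. This stand-in emulates that measurement generically: per
#' repetition it simulates one unimodal condition with the full observer
#' (total variance: image + self-movement) and once with the self-movement
#' noise switched off (image-only variance), fits both, and subtracts the
#' fitted variances. The three subtractions feed [estimate_sigma_sm()].
#'
#' @param params [observer_params()].
#' @param n_repetitions Number of repetitions (default 3).
#' @param n_reps Trials per gain per condition (default 30).
#' @param gains Gain grid.
#' @param seed Integer seed.
#' @return An [estimate_sigma_sm()] result (gain units squared).
#' @export
simulate_sm_repetitions <- function(params, n_repetitions = 3, n_reps = 30,
                                    gains = gain_grid(), seed = NULL) {
  params_noSM <- params
  params_noSM$sigma_sm <- 0
  cond <- condition("audio")
  reps <- with_seed(seed, vapply(seq_len(n_repetitions), function(r) {
    t_tot <- simulate_trials(params, n_reps = n_reps, gains = gains,
                             conditions = cond, seed = NULL)
    t_img <- simulate_trials(params_noSM, n_reps = n_reps, gains = gains,
                             conditions = cond, seed = NULL)
    f_tot <- fit_cumulative_gaussian(bin_responses(t_tot))
    f_img <- fit_cumulative_gaussian(bin_responses(t_img))
    variance_sum_law(f_tot$sigma^2, f_img$sigma^2)
  }, numeric(1)))
  estimate_sigma_sm(reps)
}

#' Analyze one simulated or measured participant
#'
#' Fits all eight conditions, derives the unimodal predicting estimates,
#' produces the three model predictions for every audio-visual condition,
#' and evaluates them: squared errors against the fitted AV parameters and
#' RMSE of the model-implied curves against the observed proportions.
#'
#' @param trials Trial table for one participant.
#' @param shared A [shared_noise()] object (gain units squared) — the
#'   separately measured self-movement variance.
#' @param boot_n Bootstrap replicates per condition (0 = none).
#' @param seed Optional seed for bootstraps.
#' @return List: `fits`, `predictions`, `errors` (squared-error rows),
#'   `rmse` (model-implied-curve RMSE rows), `av_data` (binned AV data).
#' @export
analyze_participant <- function(trials, shared, boot_n = 0, seed = NULL) {
  fits <- fit_participant(trials, boot_n = boot_n, seed = seed)
  est <- unimodal_estimates_from_fits(fits)
  preds <- predict_all(est, shared)
  av_labels <- predicting_pairs()$av_label
  av_data <- lapply(stats::setNames(av_labels, av_labels), function(lbl)
    bin_responses(trials[trials$label == lbl, ]))
  pid <- trials$participant_id[1]
  errors <- squared_errors(preds, fits, participant_id = pid)
  rmse_tab <- model_rmse_table(av_data, preds)
  rmse_tab <- cbind(participant_id = pid, rmse_tab)
  list(fits = fits, predictions = preds, errors = errors, rmse = rmse_tab,
       av_data = av_data)
}

#' Run the full simulate-fit-predict-evaluate pipeline
#'
#' Simulates a cohort from a configuration, analyzes every participant, and
#' writes the report bundle (error tables, RMSE table, rankings, summary
#' JSON) to `out_dir`.
#'
#' @param config A configuration list as from [read_config()], or a path to
#'   a JSON config file.
#' @param out_dir Output directory.
#' @param seed Overrides the config seed when non-`NULL`.
#' @param boot_n Bootstrap replicates per condition (default 0 for speed;
#'   the reference analysis uses 2000).
#' @return Invisibly, a list with the cohort tables and per-participant
#'   results.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, boot_n = 0) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- seed
  params <- config$params
  shared <- shared_noise((params$sigma_sm / params$head_mu)^2, reps_used = 3L)
  results <- list()
  for (i in seq_along(config$participants)) {
    pid <- config$participants[i]
    trials <- simulate_trials(params, n_reps = config$n_reps,
                              gains = config$gains,
                              seed = config$seed + 1000L * i,
                              participant_id = pid)
    results[[pid]] <- analyze_participant(trials, shared, boot_n = boot_n,
                                          seed = config$seed + 1000L * i)
  }
  errors <- do.call(rbind, lapply(results, `[[`, "errors"))
  rmse_tab <- do.call(rbind, lapply(results, `[[`, "rmse"))
  rownames(errors) <- rownames(rmse_tab) <- NULL
  tables <- list(
    error_table = errors,
    error_table_cohort = cohort_error_table(errors),
    rmse_table = rmse_tab,
    precision_ranking = rank_models(errors, "sq_err_precision")$ranking,
    rmse_ranking = rank_models(rmse_tab, "rmse")$ranking)
  report(tables, out_dir, config = config$raw, seed = config$seed)
  invisible(c(tables, list(participants = results)))
}
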