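#' Squared prediction errors for one participant
#'
#' Squared differences between model-predicted and empirically fitted
#' audio-visual parameters, per (condition, model). Bias errors are not
#' defined for the ICI model (its predicted bias is identically 0 by
#' assumption, so it is excluded from bias comparisons and carries `NA`).
#'
#' @param predictions Data frame from [predict_all()] (columns `condition`,
#'   `model`, `pse_av`, `sigma_av`).
#' @param empirical Named list keyed by AV condition label; each element a
#'   `psychfit` or list with `alpha` (PSE) and `sigma`.
#' @param participant_id Optional label attached to the rows.
#' @return Data frame: `participant_id`, `condition`, `model`,
#'   `sq_err_precision`, `sq_err_bias`.
#' @export
squared_errors <- function(predictions, empirical, participant_id = NA) {
  missing <- setdiff(unique(predictions$condition), names(empirical))
  if (length(missing))
    stop_validation(paste0("missing empirical fit(s): ",
                           paste(missing, collapse = ", ")))
  emp_pse <- vapply(predictions$condition, function(cc) {
    e <- empirical[[cc]]
    if (!is.null(e$alpha)) e$alpha else e$pse
  }, numeric(1))
  emp_sigma <- vapply(predictions$condition,
                      function(cc) empirical[[cc]]$sigma, numeric(1))
  out <- data.frame(
    participant_id = participant_id,
    condition = predictions$condition,
    model = predictions$model,
    sq_err_precision = (predictions$sigma_av - emp_sigma)^2,
    sq_err_bias = ifelse(predictions$model == "ICI", NA_real_,
                         (predictions$pse_av - emp_pse)^2),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohort mean and SD of squared errors
#'
#' Aggregates per-participant [squared_errors()] tables across a cohort.
#'
#' @param tables List of per-participant error tables (or one long table).
#' @return Data frame keyed by (condition, model) with mean and SD of the
#'   precision and bias squared errors and `n_participants`.
#' @export
cohort_error_table <- function(tables) {
  long <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  key <- interaction(long$condition, long$model, drop = TRUE)
  agg <- function(x, f) tapply(x, key, f)
  sd_pop <- function(x) stats::sd(x[!is.na(x)])
  out <- data.frame(
    condition = tapply(long$condition, key, `[`, 1),
    model = tapply(long$model, key, `[`, 1),
    mean_sq_err_precision = agg(long$sq_err_precision,
                                function(x) mean(x, na.rm = TRUE)),
    sd_sq_err_precision = agg(long$sq_err_precision, sd_pop),
    mean_sq_err_bias = agg(long$sq_err_bias,
                           function(x) mean(x, na.rm = TRUE)),
    sd_sq_err_bias = agg(long$sq_err_bias, sd_pop),
    n_participants = as.integer(agg(long$participant_id,
                                    function(x) length(unique(x)))),
    stringsAsFactors = FALSE)
  out <- out[order(out$condition, out$model), ]
  rownames(out) <- NULL
  out
}

#' Bootstrap confidence interval for a prediction-minus-empirical difference
#'
#' Percentile CI of the replicate-wise difference between paired bootstrap
#' samples of a model prediction and of the corresponding empirical
#' parameter. A CI excluding 0 flags an individually significant
#' mispredicton.
#'
#' @param pred_samples,emp_samples Paired numeric replicate vectors (equal
#'   length; pairing is by index).
#' @param level Confidence level (default 0.95).
#' @param parameter Label, e.g. `"precision"` or `"bias"`.
#' @return Object of class `difference_ci`: `parameter`, `lower`, `upper`,
#'   `contains_zero`, `n_boot`, `low_replicates` flag (fewer than 100 pairs).
#' @export
bootstrap_difference_ci <- function(pred_samples, emp_samples, level = 0.95,
                                    parameter = "precision") {
  keep <- is.finite(pred_samples) & is.finite(emp_samples)
  if (length(pred_samples) != length(emp_samples))
    stop_validation("replicate vectors must be paired (equal length)")
  d <- pred_samples[keep] - emp_samples[keep]
  n <- length(d)
  low <- n < 100L
  if (low) warning("fewer than 100 retained bootstrap replicates")
  qs <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(
    list(parameter = parameter, lower = qs[1], upper = qs[2],
         contains_zero = qs[1] <= 0 && 0 <= qs[2], n_boot = n,
         low_replicates = low),
    class = "difference_ci")
}

#' Bootstrap CIs of prediction-minus-empirical differences, per condition
#'
#' Applies the model equations per bootstrap replicate of the unimodal fits
#' (replicates paired by index) to propagate fitting uncertainty into the
#' model predictions, and builds percentile CIs of the replicate-wise
#' difference between each prediction and the empirical audio-visual
#' parameter. Replicates for which BCI+ is inconsistent (`rho >= 1`) or the
#' ICI image variance is negative are excluded, mirroring the exclusion
#' rule for negative self-movement variances; exclusion counts are
#' reported.
#'
#' @param fits Named fit list (as from [fit_participant()] with
#'   `boot_n > 0`): the four predicting conditions and four AV conditions,
#'   each carrying a `boot` element.
#' @param shared A [shared_noise()] object, or a numeric vector of
#'   per-replicate `sigma_sm^2` samples (recycled to the replicate count).
#' @param level Confidence level (default 0.95).
#' @return Data frame keyed by (condition, model, parameter) with `lower`,
#'   `upper`, `contains_zero`, `n_boot`, `n_excluded`.
#' @export
bootstrap_prediction_cis <- function(fits, shared, level = 0.95) {
  pairs <- predicting_pairs()
  ssq <- if (inherits(shared, "shared_noise")) shared$sigma_sm_sq else shared
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    need <- c(pairs$audio_pred_label[i], pairs$visual_pred_label[i],
              pairs$av_label[i])
    boots <- lapply(need, function(lbl) {
      f <- fits[[lbl]]
      if (is.null(f$boot))
        stop_validation(paste0("no bootstrap samples for condition ", lbl))
      f$boot$samples
    })
    n <- min(vapply(boots, nrow, integer(1)))
    a_s <- boots[[1]][seq_len(n), ]
    v_s <- boots[[2]][seq_len(n), ]
    av_s <- boots[[3]][seq_len(n), ]
    ssq_i <- rep_len(ssq, n)
    for (model in c("BCI", "BCI+", "ICI")) {
      pred_pse <- pred_sig <- rep(NA_real_, n)
      for (b in seq_len(n)) {
        a <- list(pse = a_s$alpha[b], sigma = a_s$sigma[b])
        v <- list(pse = v_s$alpha[b], sigma = v_s$sigma[b])
        pr <- tryCatch(switch(model,
          BCI = bci_predict(a, v),
          `BCI+` = bci_plus_predict(a, v,
                                    compute_rho(ssq_i[b], a$sigma, v$sigma)),
          ICI = ici_predict(a, v, ssq_i[b])),
          avmotion_error = function(e) NULL)
        if (!is.null(pr)) {
          pred_pse[b] <- pr$pse_av
          pred_sig[b] <- pr$sigma_av
        }
      }
      keep <- !is.na(pred_sig)
      for (param in c("precision", "bias")) {
        if (param == "bias" && model == "ICI") next
        pred <- if (param == "precision") pred_sig[keep] else pred_pse[keep]
        emp <- if (param == "precision") av_s$sigma[keep] else av_s$alpha[keep]
        ci <- bootstrap_difference_ci(pred, emp, level = level,
                                      parameter = param)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = pairs$av_label[i], model = model, parameter = param,
          lower = ci$lower, upper = ci$upper,
          contains_zero = ci$contains_zero,
          n_boot = ci$n_boot, n_excluded = sum(!keep),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RMSE of model-implied curves against observed proportions
#'
#' For each audio-visual condition and model, maps the predicted
#' `(pse, sigma)` to an implied psychometric curve — the standard cumulative
#' Gaussian, or the across-trial-noise curve when head-speed distributions
#' are supplied (the predicted gain-unit SD is converted to amplitude units
#' by the condition's mean head speed) — and computes the RMSE against the
#' observed proportions.
#'
#' @param av_data Named list of [binned_data()] keyed by AV condition label.
#' @param predictions [predict_all()] output.
#' @param head_dists Optional named list of [fit_velocity_distribution()]
#'   objects keyed by AV condition label; when given, the across-trial
#'   implied curve is used.
#' @return Data frame: `condition`, `model`, `rmse`.
#' @export
model_rmse_table <- function(av_data, predictions, head_dists = NULL) {
  missing <- setdiff(unique(predictions$condition), names(av_data))
  if (length(missing))
    stop_validation(paste0("missing binned data for: ",
                           paste(missing, collapse = ", ")))
  rows <- lapply(seq_len(nrow(predictions)), function(i) {
    cc <- predictions$condition[i]
    dat <- av_data[[cc]]
    obs <- dat$n_with / dat$n_total
    pred <- if (is.null(head_dists)) {
      psy_prob(dat$gain, predictions$pse_av[i], predictions$sigma_av[i])
    } else {
      hd <- head_dists[[cc]]
      if (is.null(hd)) stop_validation(paste0("missing head distribution: ", cc))
      across_trial_curve(dat$gain, predictions$pse_av[i],
                         predictions$sigma_av[i] * hd$mean, hd)
    }
    data.frame(condition = cc, model = predictions$model[i],
               rmse = rmse(pred, obs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank models by cohort mean error
#'
#' Orders models by their cohort-mean error and counts, per participant, how
#' often each model is strictly best (ties count for neither model).
#'
#' @param table Long data frame with columns `model`, a value column, and
#'   optionally `participant_id` and `condition`.
#' @param value_col Name of the error column (default `"rmse"`, or e.g.
#'   `"sq_err_precision"`).
#' @return List: `ranking` (data frame `model`, `mean_error`, ordered
#'   best-first; ties keep the model factor order and are flagged), and
#'   `best_counts` (per-model count of strictly-best cases over
#'   participant x condition cells, with `n_cases`).
#' @export
rank_models <- function(table, value_col = "rmse") {
  stopifnot(value_col %in% names(table))
  models <- unique(table$model)
  means <- vapply(models, function(m)
    mean(table[[value_col]][table$model == m], na.rm = TRUE), numeric(1))
  ord <- order(means)
  ranking <- data.frame(model = models[ord], mean_error = means[ord],
                        stringsAsFactors = FALSE)
  ranking$tied <- c(FALSE, diff(ranking$mean_error) == 0)
  cells <- interaction(
    if (!is.null(table$participant_id)) table$participant_id else 1,
    if (!is.null(table$condition)) table$condition else 1, drop = TRUE)
  counts <- stats::setNames(integer(length(models)), models)
  n_cases <- 0L
  for (cl in levels(cells)) {
    sub <- table[cells == cl, ]
    v <- sub[[value_col]]
    if (all(is.na(v))) next
    n_cases <- n_cases + 1L
    best <- which(v == min(v, na.rm = TRUE))
    if (length(best) == 1L)
      counts[sub$model[best]] <- counts[sub$model[best]] + 1L
  }
  list(ranking = ranking,
       best_counts = data.frame(model = names(counts),
                                n_best = as.integer(counts),
                                n_cases = n_cases,
                                stringsAsFactors = FALSE))
}

#' Write the evaluation report bundle
#'
#' Writes each table as CSV plus a JSON summary embedding the configuration
#' hash and seeds, so two runs with the same seed and config produce
#' byte-identical summaries.
#'
#' @param tables Named list of data frames (written as `<name>.csv`).
#' @param dir Output directory (created if needed).
#' @param config Optional configuration list (hashed into the summary).
#' @param seed Optional seed(s) recorded in the summary.
#' @return Invisibly, the path of the summary JSON.
#' @export
report <- function(tables, dir, config = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(tables = names(tables),
         config_hash = config_hash(config),
         seed = seed,
         package_version = as.character(utils::packageVersion("avmotion"))),
    summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary_path)
}
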