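# 32-bit djb2-style rolling hash of a configuration's canonical JSON, in
# hex. Non-cryptographic; only tags outputs with the config they came from.
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483648))
}

trial_columns <- c("participant_id", "modality", "audio_jitter",
                   "visual_jitter", "gain", "response", "head_velocity",
                   "sweep_index")

#' Write / read trial tables
#'
#' Trial tables are plain CSV with a mandatory header and the columns
#' `participant_id`, `modality`, `audio_jitter`, `visual_jitter`, `gain`,
#' `response` (encoded `"with"`/`"against"`), `head_velocity`,
#' `sweep_index`. A JSON sidecar (`<path>.meta.json`) records the config
#' hash and seed.
#'
#' @param trials Trial table (see [simulate_trials()]).
#' @param path CSV destination.
#' @param config,seed Recorded in the sidecar.
#' @return `write_trials()` invisibly returns `path`; `read_trials()` the
#'   trial data frame (with the condition `label` reconstructed).
#' @export
write_trials <- function(trials, path, config = NULL, seed = NULL) {
  stopifnot(all(trial_columns %in% names(trials)))
  utils::write.csv(trials[, trial_columns], path, row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = seed,
         n_trials = nrow(trials)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns, names(df))
  if (length(missing))
    stop_validation(paste0("trial file lacks column(s): ",
                           paste(missing, collapse = ", ")))
  if (!all(df$response %in% c("with", "against")))
    stop_validation("response must be 'with' or 'against'")
  df$audio_jitter <- as.logical(df$audio_jitter)
  df$visual_jitter <- as.logical(df$visual_jitter)
  df$label <- mapply(condition_label, df$modality, df$audio_jitter,
                     df$visual_jitter, USE.NAMES = FALSE)
  df
}

#' Write / read head or eye traces
#'
#' Two-column (`time`, `value`) or three-column (plus `confidence`) CSV with
#' a JSON sidecar declaring the sample rate and channel.
#'
#' @param trace Data frame with `time`, `value` (and optionally
#'   `confidence`).
#' @param path CSV destination.
#' @param rate Sample rate, Hz (defaults to the trace's `rate` attribute).
#' @param channel `"head_yaw"` or `"eye_azimuth"`.
#' @return `write_trace()` invisibly returns `path`; `read_trace()` the
#'   trace with `rate` and `channel` attributes restored.
#' @export
write_trace <- function(trace, path, rate = NULL, channel = "head_yaw") {
  rate <- trace_rate(trace, rate)
  cols <- intersect(c("time", "value", "confidence"), names(trace))
  utils::write.csv(trace[, cols], path, row.names = FALSE)
  jsonlite::write_json(list(rate = rate, channel = channel),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop_validation("trace sidecar (.meta.json) not found")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  attr(df, "rate") <- meta$rate
  attr(df, "channel") <- meta$channel
  df
}

#' Serialize psychometric fits to JSON
#'
#' @param fits Named list of `psychfit` / `across_trial_fit` objects (each
#'   optionally with a `boot` element holding a [bootstrap_fit()] summary).
#' @param path Destination.
#' @return Invisibly, `path`.
#' @export
write_fits_json <- function(fits, path) {
  ser <- lapply(fits, function(f) {
    rec <- unclass(f)
    if (!is.null(rec$boot) && inherits(rec$boot, "bootstrap_result")) {
      rec$boot <- list(
        n_requested = rec$boot$n_requested,
        n_retained = rec$boot$n_retained,
        se = as.list(vapply(rec$boot$samples, stats::sd, numeric(1))))
    }
    rec
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON configuration file
#'
#' The configuration holds the observer parameters, gain grid, repetition
#' count, participant labels, and seed. Any omitted field falls back to the
#' package defaults.
#'
#' @param path JSON file.
#' @return List with `params` (an [observer_params()]), `gains`, `n_reps`,
#'   `participants`, `seed`, and the raw config under `raw`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  par_args <- cfg$observer
  params <- if (is.null(par_args)) observer_params()
            else do.call(observer_params, par_args)
  list(
    params = params,
    gains = if (is.null(cfg$gains)) gain_grid() else as.numeric(cfg$gains),
    n_reps = if (is.null(cfg$n_reps)) 30L else as.integer(cfg$n_reps),
    participants = if (is.null(cfg$participants)) "sim01"
                   else as.character(cfg$participants),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    raw = cfg)
}
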