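# Seeded-RNG helper: run code under a temporary seed, restoring global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Build an interleaved trial schedule
#'
#' Crosses conditions with gain levels, repeats each cell `n_reps` times, and
#' interleaves all trial types in a seeded random order, matching a
#' method-of-constant-stimuli session in which every condition is randomly
#' mixed within blocks.
#'
#' @param n_reps Repetitions per (condition, gain) cell.
#' @param gains Numeric vector of distinct movement gains (see [gain_grid()]).
#' @param conditions Data frame of conditions as from [av_conditions()].
#' @param seed Integer seed for the interleaving order (`NULL` = current RNG).
#' @return A data frame of trial stubs (`trial`, `label`, `modality`,
#'   `audio_jitter`, `visual_jitter`, `gain`), one row per trial.
#' @export
#' @examples
#' nrow(make_schedule(30, gain_grid(), av_conditions())) # 3120
make_schedule <- function(n_reps, gains, conditions, seed = NULL) {
  stopifnot(n_reps >= 1, length(gains) >= 1)
  if (anyDuplicated(gains)) stop_validation("gains must be distinct")
  if (anyDuplicated(conditions$label))
    stop_validation("conditions must be distinct")
  cells <- merge(conditions, data.frame(gain = gains), by = NULL)
  sched <- cells[rep(seq_len(nrow(cells)), each = n_reps), ]
  ord <- with_seed(seed, sample.int(nrow(sched)))
  sched <- sched[ord, c("label", "modality", "audio_jitter",
                        "visual_jitter", "gain")]
  rownames(sched) <- NULL
  cbind(trial = seq_len(nrow(sched)), sched)
}

#' Draw per-trial median head speeds
#'
#' Head speeds follow a Gaussian truncated below at the head-speed floor
#' (stimuli vanish when the head moves more slowly than the floor, so such
#' trials are never judged). Truncation is by rejection sampling.
#'
#' @param params An [observer_params()] object.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` head speeds (deg/s), all `>= head_floor`.
#' @export
draw_head_velocity <- function(params, n, seed = NULL) {
  stopifnot(n >= 1)
  if (params$head_sd < 0) stop_validation("head_sd must be >= 0")
  with_seed(seed, {
    if (params$head_sd == 0) return(rep(params$head_mu, n))
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(2L * (n - length(out)) + 10L,
                           params$head_mu, params$head_sd)
      out <- c(out, draw[draw >= params$head_floor])
    }
    out[seq_len(n)]
  })
}

# internal, vectorized: per-trial decision variables in amplitude units.
# D_m = (gain - (1 - r_m)) * h + eps_img_m + eps_sm, with eps_sm drawn once
# per trial and shared between modalities. The AV decision variable combines
# the two with weights from the correlation-adjusted reliabilities evaluated
# at the true total noises (or plain reliabilities if av_rule = "bci").
decision_vars <- function(gain, modality, audio_jitter, visual_jitter,
                          head_speed, params) {
  n <- length(gain)
  stopifnot(length(head_speed) == n)
  eps_sm <- stats::rnorm(n, 0, params$sigma_sm)
  out <- data.frame(D_a = rep(NA_real_, n), D_v = rep(NA_real_, n),
                    D = rep(NA_real_, n))
  need_a <- modality %in% c("audio", "audio_visual")
  need_v <- modality %in% c("visual", "audio_visual")
  sig_a <- ifelse(audio_jitter, params$sigma_img_audio[2],
                  params$sigma_img_audio[1])
  sig_v <- ifelse(visual_jitter, params$sigma_img_visual[2],
                  params$sigma_img_visual[1])
  if (any(need_a)) {
    out$D_a[need_a] <- (gain[need_a] - (1 - params$r_audio)) *
      head_speed[need_a] +
      stats::rnorm(sum(need_a), 0, sig_a[need_a]) + eps_sm[need_a]
  }
  if (any(need_v)) {
    out$D_v[need_v] <- (gain[need_v] - (1 - params$r_visual)) *
      head_speed[need_v] +
      stats::rnorm(sum(need_v), 0, sig_v[need_v]) + eps_sm[need_v]
  }
  is_av <- modality == "audio_visual"
  out$D[!is_av] <- ifelse(modality[!is_av] == "audio",
                          out$D_a[!is_av], out$D_v[!is_av])
  if (any(is_av)) {
    tot_a <- sqrt(sig_a^2 + params$sigma_sm^2)
    tot_v <- sqrt(sig_v^2 + params$sigma_sm^2)
    # weights depend only on the jitter flags; compute once per combination
    w_a <- numeric(n)
    combo <- paste(audio_jitter, visual_jitter)
    for (cb in unique(combo[is_av])) {
      i <- which(is_av & combo == cb)[1]
      au <- unimodal_estimate("audio", 0, tot_a[i])
      vi <- unimodal_estimate("visual", 0, tot_v[i])
      pr <- if (params$av_rule == "bci_plus") {
        # with zero image noise rho -> 1; clamp: the cues are then identical
        # and any convex weighting yields the same decision variable
        rho <- min(params$sigma_sm^2 / (tot_a[i] * tot_v[i]), 1 - 1e-9)
        bci_plus_predict(au, vi, rho)
      } else bci_predict(au, vi)
      w_a[is_av & combo == cb] <- pr$w_a
    }
    out$D[is_av] <- w_a[is_av] * out$D_a[is_av] +
      (1 - w_a[is_av]) * out$D_v[is_av]
  }
  out
}

#' Simulate one binary direction judgment
#'
#' Applies the generative observer to a single trial: the body-centered
#' amplitude estimate for each present modality is
#' `D_m = (gain - (1 - r_m)) * h + eps_img_m + eps_sm`, where `eps_sm` is the
#' self-movement noise drawn once and shared between modalities; the response
#' is `"with"` iff the (combined) decision variable is positive, and with
#' probability `lapse` the response is replaced by a fair coin flip. Uses the
#' current RNG state; see [simulate_trials()] for the seeded batch interface.
#'
#' @param gain Movement gain of the trial.
#' @param cond One-row condition data frame (see [condition()]).
#' @param head_velocity Signed per-trial median head velocity, deg/s; its
#'   magnitude must be at least `params$head_floor`.
#' @param params [observer_params()].
#' @return `"with"` or `"against"`.
#' @export
simulate_response <- function(gain, cond, head_velocity, params) {
  stopifnot(abs(head_velocity) >= params$head_floor)
  d <- decision_vars(gain, cond$modality, cond$audio_jitter,
                     cond$visual_jitter, abs(head_velocity), params)
  resp <- if (d$D > 0) "with" else "against"
  if (stats::runif(1) < params$lapse)
    resp <- sample(c("with", "against"), 1L)
  resp
}

#' Simulate a full experiment for one observer
#'
#' Generates a schedule (or takes one), draws per-trial head speeds from the
#' truncated head-speed distribution, simulates every judgment, and returns a
#' tidy per-trial table. The judged sweep is the third head sweep; each trial
#' carries one signed median head velocity (sweep direction alternates with
#' the trial's random starting direction).
#'
#' @param params [observer_params()].
#' @param n_reps Repetitions per (condition, gain) cell (default 30).
#' @param gains Gain levels (default [gain_grid()]).
#' @param conditions Conditions (default [av_conditions()]).
#' @param seed Integer seed controlling schedule order, head speeds, and
#'   responses.
#' @param participant_id Label stored in the table.
#' @param schedule Optional pre-built schedule from [make_schedule()].
#' @return A data frame of trial records: `participant_id`, `label`,
#'   `modality`, `audio_jitter`, `visual_jitter`, `gain`, `response`
#'   (`"with"`/`"against"`), `head_velocity` (signed deg/s), `sweep_index`.
#' @export
#' @examples
#' trials <- simulate_trials(observer_params(), n_reps = 2, seed = 1)
#' table(trials$label)
simulate_trials <- function(params, n_reps = 30, gains = gain_grid(),
                            conditions = av_conditions(), seed = NULL,
                            participant_id = "sim01", schedule = NULL) {
  with_seed(seed, {
    if (is.null(schedule))
      schedule <- make_schedule(n_reps, gains, conditions, seed = NULL)
    n <- nrow(schedule)
    speed <- draw_head_velocity(params, n, seed = NULL)
    dir <- sample(c(-1, 1), n, replace = TRUE)
    d <- decision_vars(schedule$gain, schedule$modality,
                       schedule$audio_jitter, schedule$visual_jitter,
                       speed, params)
    resp <- ifelse(d$D > 0, "with", "against")
    lapse_hit <- stats::runif(n) < params$lapse
    if (any(lapse_hit))
      resp[lapse_hit] <- sample(c("with", "against"), sum(lapse_hit),
                                replace = TRUE)
    data.frame(
      participant_id = participant_id,
      label = schedule$label,
      modality = schedule$modality,
      audio_jitter = schedule$audio_jitter,
      visual_jitter = schedule$visual_jitter,
      gain = schedule$gain,
      response = resp,
      head_velocity = dir * speed,
      sweep_index = 3L,
      stringsAsFactors = FALSE
    )
  })
}

#' Closed-form psychometric parameters of the generative observer
#'
#' For a fixed head speed (`head_sd = 0`) the observer's psychometric
#' function is an exact cumulative Gaussian in gain units: unimodal PSE is
#' `1 - r_m` and SD is `sqrt(sigma_img_m^2 + sigma_sm^2) / head_mu`; the
#' audio-visual parameters follow from the correlated-cue combination of the
#' two unimodal values with `rho = sigma_sm^2 / (sigma_a sigma_v)` (or the
#' plain combination when `av_rule = "bci"`). Used as the oracle for
#' parameter-recovery tests. With across-trial head-speed variability there
#' is no closed form and a typed error is raised.
#'
#' @param params [observer_params()] with `head_sd = 0`.
#' @param cond One-row condition data frame.
#' @return List with `pse` and `sigma` (gain units); for audio-visual
#'   conditions also `rho`, `w_a`, `w_v`.
#' @export
analytic_psychometric <- function(params, cond) {
  if (params$head_sd != 0)
    stop(errorCondition(
      "no closed form with head-speed variability (head_sd != 0)",
      class = c("avmotion_not_applicable", "avmotion_error")))
  h <- params$head_mu
  uni <- function(modality, jitter) {
    mn <- modality_noise(params, modality, jitter)
    list(pse = 1 - mn$r,
         sigma = sqrt(mn$sigma_img^2 + params$sigma_sm^2) / h)
  }
  if (cond$modality %in% c("audio", "visual")) {
    jit <- if (cond$modality == "audio") cond$audio_jitter else cond$visual_jitter
    return(uni(cond$modality, jit))
  }
  a <- uni("audio", cond$audio_jitter)
  v <- uni("visual", cond$visual_jitter)
  au <- unimodal_estimate("audio", a$pse, a$sigma)
  vi <- unimodal_estimate("visual", v$pse, v$sigma)
  pr <- if (params$av_rule == "bci_plus") {
    rho <- compute_rho((params$sigma_sm / h)^2, a$sigma, v$sigma)
    bci_plus_predict(au, vi, rho)
  } else bci_predict(au, vi)
  list(pse = pr$pse_av, sigma = pr$sigma_av, rho = pr$rho,
       w_a = pr$w_a, w_v = pr$w_v)
}
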