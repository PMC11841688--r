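#' Generative observer parameters
#'
#' Parameters of the generative observer used by the simulator. All noise
#' magnitudes are specified in amplitude units (deg/s): the observer judges
#' motion amplitude, not motion gain, so amplitude noises are divided by the
#' head speed to produce gain-unit psychometric parameters. Each modality has
#' its own image-noise SD, separately for jittered and non-jittered stimuli,
#' and its own compensation gain `r` (1 = perfect compensation for the head
#' movement; `r < 1` yields a Filehne-type bias with PSE `1 - r` in gain
#' units). A single self-movement noise SD `sigma_sm` is shared between the
#' compensated auditory and visual cues on every trial.
#'
#' @param sigma_img_audio,sigma_img_visual Length-2 numeric vectors,
#'   image-noise SD in deg/s as `c(plain, jittered)`; a scalar is recycled.
#' @param sigma_sm Shared self-movement noise SD, deg/s.
#' @param r_audio,r_visual Compensation gains (dimensionless).
#' @param head_mu,head_sd Mean and SD of the per-trial median head speed,
#'   deg/s.
#' @param head_floor Minimum head speed (deg/s); stimuli vanish below it, so
#'   retained trials satisfy `speed >= head_floor`. Default 15.
#' @param lapse Probability of a stimulus-independent response, in [0, 0.02].
#' @param av_rule Audio-visual combination rule for the generative observer:
#'   `"bci_plus"` (correlation-adjusted weights; the default, which makes
#'   parameter recovery against the BCI+ model exact by construction) or
#'   `"bci"` (plain reliability weights, for model-discrimination tests).
#' @return An object of class `observer_params`.
#' @export
#' @examples
#' observer_params()
observer_params <- function(sigma_img_audio = c(14, 20),
                            sigma_img_visual = c(8, 16),
                            sigma_sm = 6,
                            r_audio = 0.97,
                            r_visual = 0.90,
                            head_mu = 80,
                            head_sd = 10,
                            head_floor = 15,
                            lapse = 0.01,
                            av_rule = c("bci_plus", "bci")) {
  av_rule <- match.arg(av_rule)
  sigma_img_audio <- rep_len(as.numeric(sigma_img_audio), 2L)
  sigma_img_visual <- rep_len(as.numeric(sigma_img_visual), 2L)
  if (any(c(sigma_img_audio, sigma_img_visual, sigma_sm) < 0))
    stop_validation("noise SDs must be >= 0")
  if (head_sd < 0) stop_validation("head_sd must be >= 0")
  if (!(head_mu > head_floor)) stop_validation("head_mu must exceed head_floor")
  if (head_floor < 0) stop_validation("head_floor must be >= 0")
  if (lapse < 0 || lapse > 0.02)
    stop_validation("lapse must lie in [0, 0.02]")
  structure(
    list(
      sigma_img_audio = sigma_img_audio,
      sigma_img_visual = sigma_img_visual,
      sigma_sm = sigma_sm,
      r_audio = r_audio,
      r_visual = r_visual,
      head_mu = head_mu,
      head_sd = head_sd,
      head_floor = head_floor,
      lapse = lapse,
      av_rule = av_rule
    ),
    class = "observer_params"
  )
}

#' Observer parameters specified in gain units
#'
#' Convenience constructor: noises given in gain units at a reference head
#' speed are converted to amplitude units (multiplied by `head_mu`).
#'
#' @param sigma_img_audio,sigma_img_visual,sigma_sm Noise SDs in gain units.
#' @param ... Passed on to [observer_params()] (notably `head_mu`).
#' @return An `observer_params` object.
#' @export
observer_params_gain <- function(sigma_img_audio, sigma_img_visual,
                                 sigma_sm, ...) {
  dots <- list(...)
  head_mu <- if (!is.null(dots$head_mu)) dots$head_mu else 80
  observer_params(
    sigma_img_audio = sigma_img_audio * head_mu,
    sigma_img_visual = sigma_img_visual * head_mu,
    sigma_sm = sigma_sm * head_mu,
    ...
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Generative observer (amplitude units, deg/s)\n")
  cat(sprintf("  image noise  audio: %.3g (plain) / %.3g (jitter)\n",
              x$sigma_img_audio[1], x$sigma_img_audio[2]))
  cat(sprintf("  image noise visual: %.3g (plain) / %.3g (jitter)\n",
              x$sigma_img_visual[1], x$sigma_img_visual[2]))
  cat(sprintf("  shared self-movement noise: %.3g\n", x$sigma_sm))
  cat(sprintf("  compensation gains: audio %.3g, visual %.3g\n",
              x$r_audio, x$r_visual))
  cat(sprintf("  head speed: mean %.3g, sd %.3g, floor %.3g deg/s\n",
              x$head_mu, x$head_sd, x$head_floor))
  cat(sprintf("  lapse: %.3g; AV rule: %s\n", x$lapse, x$av_rule))
  invisible(x)
}

# internal: per-modality image-noise SD and compensation gain for a condition
modality_noise <- function(params, modality, jitter) {
  idx <- if (jitter) 2L else 1L
  switch(modality,
    audio = list(sigma_img = params$sigma_img_audio[idx], r = params$r_audio),
    visual = list(sigma_img = params$sigma_img_visual[idx], r = params$r_visual),
    stop_validation("modality must be 'audio' or 'visual'")
  )
}
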