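#' Canonical movement-gain grid
#'
#' The experimental design probes stimulus motion at a signed proportion of
#' the concurrent head speed ("movement gain"). The canonical grid spans
#' 0 to +/-0.5 in seven steps per side, 13 distinct values in total,
#' symmetric about 0.
#'
#' @param max_gain Largest absolute gain (default 0.5).
#' @param n_steps Number of steps from 0 to `max_gain` inclusive of the
#'   endpoint but excluding 0 (default 6, giving 13 levels in total).
#' @return Numeric vector of 13 gains, sorted increasing.
#' @export
#' @examples
#' gain_grid()
gain_grid <- function(max_gain = 0.5, n_steps = 6) {
  stopifnot(max_gain > 0, n_steps >= 1)
  pos <- seq(0, max_gain, length.out = n_steps + 1L)
  sort(unique(c(-pos, pos)))
}

#' Construct a stimulus condition
#'
#' A condition is a modality (audio, visual, or audio-visual) plus positional
#' jitter flags per modality. Jitter can only be applied to a modality that is
#' present: audio-only conditions cannot carry visual jitter and vice versa.
#'
#' @param modality One of `"audio"`, `"visual"`, `"audio_visual"`.
#' @param audio_jitter,visual_jitter Logical jitter flags.
#' @return A one-row data frame with columns `modality`, `audio_jitter`,
#'   `visual_jitter`, and a `label` identifying the condition.
#' @export
condition <- function(modality = c("audio", "visual", "audio_visual"),
                      audio_jitter = FALSE, visual_jitter = FALSE) {
  modality <- match.arg(modality)
  stopifnot(is.logical(audio_jitter), is.logical(visual_jitter),
            length(audio_jitter) == 1L, length(visual_jitter) == 1L)
  if (modality == "visual" && audio_jitter)
    stop_validation("audio jitter is not applicable to a visual-only condition")
  if (modality == "audio" && visual_jitter)
    stop_validation("visual jitter is not applicable to an audio-only condition")
  data.frame(
    modality = modality,
    audio_jitter = audio_jitter,
    visual_jitter = visual_jitter,
    label = condition_label(modality, audio_jitter, visual_jitter),
    stringsAsFactors = FALSE
  )
}

condition_label <- function(modality, audio_jitter, visual_jitter) {
  jit <- c(if (audio_jitter) "aj", if (visual_jitter) "vj")
  paste0(abbreviate_modality(modality),
         if (length(jit)) paste0("_", paste(jit, collapse = "")) else "")
}

abbreviate_modality <- function(modality) {
  c(audio = "a", visual = "v", audio_visual = "av")[[modality]]
}

#' The eight interleaved experimental conditions
#'
#' Visual and audio stimuli each with and without positional jitter, plus the
#' four audio-visual combinations of the two jitter flags.
#'
#' @return An 8-row data frame (columns `modality`, `audio_jitter`,
#'   `visual_jitter`, `label`).
#' @export
#' @examples
#' av_conditions()
av_conditions <- function() {
  rows <- list(
    condition("visual"),
    condition("visual", visual_jitter = TRUE),
    condition("audio"),
    condition("audio",  audio_jitter = TRUE),
    condition("audio_visual"),
    condition("audio_visual", visual_jitter = TRUE),
    condition("audio_visual", audio_jitter = TRUE),
    condition("audio_visual", audio_jitter = TRUE, visual_jitter = TRUE)
  )
  do.call(rbind, rows)
}

# internal: classed validation error shared across the package
stop_validation <- function(msg, class = "avmotion_validation_error") {
  stop(errorCondition(msg, class = c(class, "avmotion_error")))
}
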