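#' Synthetic multi-sweep head trace
#'
#' Constant-speed back-and-forth yaw trajectory: the head moves between
#' `-amplitude` and `+amplitude` at `speed` deg/s, one direction reversal per
#' sweep. Used to exercise the kinematics pipeline with a known generative
#' median velocity.
#'
#' @param speed Head speed, deg/s.
#' @param amplitude Half-excursion, deg.
#' @param n_sweeps Number of sweeps (direction segments).
#' @param rate Sample rate, Hz (default 240, the head-tracker rate).
#' @return A data frame `time` (s), `value` (deg) with attribute `rate`.
#' @export
simulate_head_trace <- function(speed = 80, amplitude = 20, n_sweeps = 5,
                                rate = 240) {
  stopifnot(speed > 0, amplitude > 0, n_sweeps >= 1, rate > 0)
  sweep_dur <- 2 * amplitude / speed
  n_per <- round(sweep_dur * rate)
  pos <- numeric(0)
  x <- -amplitude
  dir <- 1
  for (s in seq_len(n_sweeps)) {
    pos <- c(pos, x + dir * speed * seq_len(n_per) / rate)
    x <- x + dir * speed * n_per / rate
    dir <- -dir
  }
  out <- data.frame(time = seq_along(pos) / rate, value = pos)
  attr(out, "rate") <- rate
  out
}

#' Gain-coded stimulus trace with optional positional jitter
#'
#' World-frame stimulus position is `gain` times the head displacement from
#' trace onset, plus (when `jitter` is on) a piecewise-constant random offset
#' drawn uniformly from `[-jitter_half, +jitter_half]` and redrawn at
#' `jitter_rate` Hz.
#'
#' @param head Head-position trace: data frame with `time` and `value`
#'   columns (deg) sampled uniformly at `rate`.
#' @param gain Movement gain.
#' @param jitter Logical; add positional jitter?
#' @param rate Sample rate in Hz; defaults to the trace's `rate` attribute.
#' @param jitter_half Half-width of the jitter distribution, deg (default
#'   7.5, i.e., uniform on [-7.5, +7.5]).
#' @param jitter_rate Jitter refresh rate, Hz (default 5).
#' @param seed Optional integer seed for the jitter sequence.
#' @return Data frame `time`, `position` (deg), `jitter_applied`.
#' @export
generate_stimulus_trace <- function(head, gain, jitter = FALSE, rate = NULL,
                                    jitter_half = 7.5, jitter_rate = 5,
                                    seed = NULL) {
  if (is.null(rate)) rate <- attr(head, "rate")
  if (is.null(rate)) stop_validation("sample rate must be declared")
  disp <- head$value - head$value[1]
  pos <- gain * disp
  if (jitter) {
    n <- length(pos)
    hold <- max(1L, round(rate / jitter_rate))   # samples per jitter epoch
    n_epochs <- ceiling(n / hold)
    offsets <- with_seed(seed,
                         stats::runif(n_epochs, -jitter_half, jitter_half))
    pos <- pos + offsets[ceiling(seq_len(n) / hold)]
  }
  data.frame(time = head$time, position = pos, jitter_applied = jitter)
}

#' Leaky-integrator stimulus gating
#'
#' Stimulus amplitude/luminance level as a function of head speed: the level
#' starts at 1 and is halved (more generally multiplied by `1 - decay`) for
#' every frame spent below the speed threshold; it resets to 1 as soon as the
#' speed returns above threshold.
#'
#' @param head_speed Per-frame head speed series, deg/s.
#' @param threshold Speed threshold, deg/s (default 15).
#' @param decay Fractional loss per sub-threshold frame in (0, 1] (default
#'   0.5).
#' @return Numeric level series in `[0, 1]`, same length as `head_speed`.
#' @export
#' @examples
#' gate_stimulus_level(c(20, 10, 10, 10, 20), threshold = 15) # decays, resets
gate_stimulus_level <- function(head_speed, threshold = 15, decay = 0.5) {
  if (!(threshold > 0)) stop_validation("threshold must be > 0")
  if (!(decay > 0 && decay <= 1)) stop_validation("decay must be in (0, 1]")
  level <- numeric(length(head_speed))
  cur <- 1
  for (i in seq_along(head_speed)) {
    cur <- if (head_speed[i] < threshold) cur * (1 - decay) else 1
    level[i] <- cur
  }
  level
}
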