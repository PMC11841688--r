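# Zero-phase FFT-domain filtering with reflection padding. `mag_fun` maps a
# vector of nonnegative frequencies (Hz) to gains in [0, 1]; the response is
# real and even, so the filter has exactly zero phase.
fft_filter <- function(x, rate, mag_fun) {
  n <- length(x)
  pad <- min(n - 1L, max(16L, ceiling(rate)))    # ~1 s reflection each side
  xe <- c(2 * x[1] - rev(x[2:(pad + 1L)]),
          x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  m <- length(xe)
  f <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1L, -1L)) * rate / m
  xf <- stats::fft(xe) * mag_fun(abs(f))
  Re(stats::fft(xf, inverse = TRUE))[pad + seq_len(n)] / m
}

trace_rate <- function(trace, rate) {
  if (is.null(rate)) rate <- attr(trace, "rate")
  if (is.null(rate)) stop_validation("sample rate must be declared")
  rate
}

#' Zero-phase lowpass filter for head traces
#'
#' Smooths a head-position trace with a zero-phase lowpass whose -3 dB point
#' sits at the passband edge. Implemented as FFT-domain multiplication by a
#' Butterworth magnitude response of order 10 (about 60 dB attenuation one
#' octave above the passband), with reflection padding against edge
#' transients; DC gain is exactly 1.
#'
#' @param trace Data frame with a `value` column (deg), uniformly sampled.
#' @param passband -3 dB frequency, Hz (default 8). Must be below Nyquist.
#' @param rate Sample rate, Hz; defaults to the trace's `rate` attribute.
#' @param order Butterworth magnitude order (default 10).
#' @return The trace with `value` replaced by the filtered signal.
#' @export
lowpass_head <- function(trace, passband = 8, rate = NULL, order = 10) {
  rate <- trace_rate(trace, rate)
  if (!(passband > 0 && passband < rate / 2))
    stop_validation("passband must lie in (0, Nyquist)")
  trace$value <- fft_filter(trace$value, rate,
                            function(f) 1 / sqrt(1 + (f / passband)^(2 * order)))
  trace
}

# Frequency-domain Gaussian smoothing: spectrum times exp(-f^2 / (2 sigma^2)).
gaussian_smooth <- function(x, rate, sigma_f = 16) {
  fft_filter(x, rate, function(f) exp(-f^2 / (2 * sigma_f^2)))
}

#' Causal turn detection via a finite-difference filter
#'
#' The head-position derivative is smoothed by convolving samples with a
#' finite-difference filter of length `filter_len` applied causally (the
#' smoothed derivative at sample i is the mean slope over the preceding
#' `filter_len - 1` intervals). A turn is flagged at the first sample whose
#' smoothed derivative has the opposite sign to the preceding non-zero sign.
#' On a noise-free triangle wave with reversal at sample k the detection
#' falls at `k + (filter_len + 1)/2` (7 samples, ~30 ms at 240 Hz, for the
#' default 13-sample filter).
#'
#' @param trace Data frame with `value`, or a numeric position vector.
#' @param filter_len Odd filter length >= 3 (default 13).
#' @return Integer vector of detection sample indices (possibly empty).
#' @export
detect_turn <- function(trace, filter_len = 13) {
  x <- if (is.data.frame(trace)) trace$value else trace
  if (filter_len < 3 || filter_len %% 2 == 0)
    stop_validation("filter_len must be odd and >= 3")
  n <- length(x)
  if (n < filter_len) stop_validation("trace shorter than the filter")
  L <- filter_len
  idx <- L:n
  s <- (x[idx] - x[idx - (L - 1L)]) / (L - 1L)
  sg <- sign(s)
  detections <- integer(0)
  last <- 0
  for (i in seq_along(sg)) {
    if (sg[i] != 0) {
      if (last != 0 && sg[i] != last) detections <- c(detections, idx[i])
      last <- sg[i]
    }
  }
  detections
}

#' Segment a trace into sweeps at direction reversals
#'
#' Noise-free reversal detection: sign changes of the central-difference
#' derivative, with ties at zero derivative broken toward the earlier sample.
#'
#' @param trace Data frame with `value`, or numeric positions.
#' @param judged_sweep Index of the sweep carrying the judged stimulus
#'   (default 3).
#' @return An object of class `sweep_segmentation`: `boundaries` (sample
#'   indices delimiting sweeps, starting at 1 and ending at the last sample)
#'   and `judged_sweep`.
#' @export
segment_sweeps <- function(trace, judged_sweep = 3) {
  x <- if (is.data.frame(trace)) trace$value else trace
  n <- length(x)
  if (n < 3) stop_validation("trace too short to segment")
  v <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
  sg <- sign(v)
  rev_idx <- integer(0)
  last <- 0
  last_i <- 1L
  for (i in seq_len(n)) {
    if (sg[i] != 0) {
      if (last != 0 && sg[i] != last) {
        # reversal between last_i and i; tie at zero breaks earlier
        rev_idx <- c(rev_idx, if (i - last_i > 1L) last_i + 1L else last_i)
      }
      last <- sg[i]
      last_i <- i
    }
  }
  boundaries <- unique(c(1L, rev_idx, n))
  n_sweeps <- length(boundaries) - 1L
  if (judged_sweep < 1 || judged_sweep > n_sweeps)
    stop_validation(sprintf("judged_sweep %d does not exist (%d sweeps found)",
                            judged_sweep, n_sweeps))
  structure(list(boundaries = boundaries, judged_sweep = judged_sweep,
                 n_sweeps = n_sweeps),
            class = "sweep_segmentation")
}

# central-difference derivative, one-sided at the edges, in units/s
differentiate <- function(x, rate) {
  n <- length(x)
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * rate
}

#' Median head velocity over the judged sweep's region of interest
#'
#' The temporal derivative of the (filtered) head-position trace is taken and
#' its median computed over the central portion of the judged sweep —
#' by default 20% to 60% of the sweep length, a region previously shown to
#' give a stable speed estimate.
#'
#' @param trace Data frame with `value` (deg).
#' @param seg A [segment_sweeps()] result.
#' @param roi Fractional interval of the sweep, default `c(0.2, 0.6)`.
#' @param rate Sample rate, Hz; defaults to the trace's `rate` attribute.
#' @return Signed median velocity, deg/s.
#' @export
median_sweep_velocity <- function(trace, seg, roi = c(0.2, 0.6), rate = NULL) {
  rate <- trace_rate(trace, rate)
  stopifnot(inherits(seg, "sweep_segmentation"))
  if (!(roi[1] >= 0 && roi[2] <= 1 && roi[1] < roi[2]))
    stop_validation("roi must be a nonempty subinterval of [0, 1]")
  x <- trace$value
  v <- differentiate(x, rate)
  b <- seg$boundaries
  start <- b[seg$judged_sweep]
  end <- b[seg$judged_sweep + 1L]
  len <- end - start
  lo <- ceiling(start + roi[1] * len)
  hi <- floor(start + roi[2] * len)
  if (hi - lo + 1L < 3L) stop_validation("ROI shorter than 3 samples")
  stats::median(v[lo:hi])
}

#' Gaussian fit of per-trial median head velocities
#'
#' Maximum-likelihood Gaussian: sample mean and population variance
#' (divide-by-n convention).
#'
#' @param medians Numeric vector of per-trial median velocities (>= 2).
#' @return Object of class `velocity_distribution`: `mean`, `variance`,
#'   `n_trials`.
#' @export
#' @examples
#' fit_velocity_distribution(c(60, 100)) # mean 80, variance 400
fit_velocity_distribution <- function(medians) {
  if (length(medians) < 2L) stop_validation("need at least 2 trials")
  m <- mean(medians)
  structure(list(mean = m, variance = mean((medians - m)^2),
                 n_trials = length(medians)),
            class = "velocity_distribution")
}

#' Expected vestibulo-ocular reflex eye velocity
#'
#' For a head rotating at velocity `H` with the eyes offset `R` meters from
#' the rotation center and a target at distance `D` meters, perfect gaze
#' stabilization requires eye velocity `E = -H (1 + R/D)`.
#'
#' @param head_velocity `H`, deg/s (vectorized).
#' @param eye_offset_R Eye-to-rotation-center distance, m (default 0.1).
#' @param target_distance_D Target distance, m (default 1.2); must be > 0.
#' @return Expected eye velocity, deg/s.
#' @export
#' @examples
#' expected_vor(96) # -104
expected_vor <- function(head_velocity, eye_offset_R = 0.1,
                         target_distance_D = 1.2) {
  if (any(target_distance_D <= 0)) stop_validation("D must be > 0")
  -head_velocity * (1 + eye_offset_R / target_distance_D)
}
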