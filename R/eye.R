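#' Clean an eye-position trace
#'
#' Tracker samples below the confidence threshold are removed and the gaps
#' filled by linear interpolation; the whole waveform is rejected when 50% or
#' fewer samples survive thresholding (a typed outcome, not an error). The
#' surviving waveform is smoothed with a frequency-domain Gaussian
#' (`sigma_f` Hz), the first three derivatives (velocity, acceleration,
#' jerk) are computed by central differences (one-sided at the edges), and
#' the first and last `trim` samples are discarded.
#'
#' @param trace Data frame with `time` (s), `value` (deg), and `confidence`
#'   in `[0, 1]`.
#' @param conf_threshold Minimum confidence to keep a sample (default 0.6).
#' @param rate Sample rate, Hz; defaults to the trace's `rate` attribute.
#' @param sigma_f Frequency-domain Gaussian SD, Hz (default 16).
#' @param trim Samples dropped at each end after differentiation (default 20).
#' @return An object of class `eye_clean` with `time`, `position`,
#'   `velocity`, `acceleration`, `jerk`, `rate`, `n_interpolated`; or an
#'   object of class `eye_rejected` (fields `reason`, `prop_retained`) when
#'   too few samples survive.
#' @export
preprocess_eye <- function(trace, conf_threshold = 0.6, rate = NULL,
                           sigma_f = 16, trim = 20) {
  rate <- trace_rate(trace, rate)
  if (is.null(trace$confidence))
    stop_validation("a confidence channel is required")
  ok <- trace$confidence >= conf_threshold
  prop <- mean(ok)
  if (prop <= 0.5) {
    return(structure(
      list(reason = "50% or fewer samples above the confidence threshold",
           prop_retained = prop),
      class = "eye_rejected"))
  }
  x <- trace$value
  if (any(!ok))
    x <- stats::approx(trace$time[ok], x[ok], xout = trace$time,
                       rule = 2)$y
  xs <- gaussian_smooth(x, rate, sigma_f)
  vel <- differentiate(xs, rate)
  acc <- differentiate(vel, rate)
  jrk <- differentiate(acc, rate)
  n <- length(xs)
  if (n <= 2 * trim) stop_validation("trace too short after edge trimming")
  keep <- (trim + 1L):(n - trim)
  structure(
    list(time = trace$time[keep], position = xs[keep], velocity = vel[keep],
         acceleration = acc[keep], jerk = jrk[keep], rate = rate,
         n_interpolated = sum(!ok)),
    class = "eye_clean")
}

#' Jerk-based saccade rejection
#'
#' Samples whose absolute jerk exceeds the threshold — plus `pad` samples on
#' each side — are flagged as saccadic and removed from fixation analyses.
#'
#' @param jerk Jerk series, deg/s^3 (e.g., from [preprocess_eye()]).
#' @param jerk_threshold Threshold, deg/s^3 (default 20000).
#' @param pad Samples masked on each side of a detection (default 4).
#' @return Object of class `saccade_mask`: logical `keep` (TRUE = retained),
#'   `n_masked`; or class `no_valid_samples` when nothing survives.
#' @export
remove_saccades <- function(jerk, jerk_threshold = 20000, pad = 4) {
  if (jerk_threshold < 0) stop_validation("jerk_threshold must be >= 0")
  n <- length(jerk)
  bad <- abs(jerk) >= jerk_threshold
  if (any(bad) && pad > 0) {
    hits <- which(bad)
    for (i in hits) bad[max(1L, i - pad):min(n, i + pad)] <- TRUE
  }
  if (all(bad)) {
    return(structure(list(reason = "no valid samples", keep = !bad,
                          n_masked = n),
                     class = c("no_valid_samples", "saccade_mask")))
  }
  structure(list(keep = !bad, n_masked = sum(bad)), class = "saccade_mask")
}

#' Mean eye velocity and speed over the judged sweep
#'
#' Averages the cleaned eye velocity over the unmasked samples falling inside
#' the judged sweep.
#'
#' @param eye An `eye_clean` object.
#' @param mask A [remove_saccades()] result (optional; default keeps all).
#' @param seg Optional [segment_sweeps()] segmentation *of the eye trace's
#'   concurrent head trace*, in the trimmed sample indexing; default uses the
#'   whole trace.
#' @return List with `mean_velocity` and `mean_speed` (deg/s), and `n_used`;
#'   or a `no_valid_samples` outcome.
#' @export
mean_eye_velocity <- function(eye, mask = NULL, seg = NULL) {
  stopifnot(inherits(eye, "eye_clean"))
  keep <- if (is.null(mask)) rep(TRUE, length(eye$velocity)) else mask$keep
  if (!is.null(seg)) {
    b <- seg$boundaries
    idx <- seq(b[seg$judged_sweep], b[seg$judged_sweep + 1L])
    sel <- rep(FALSE, length(keep))
    sel[idx[idx <= length(sel)]] <- TRUE
    keep <- keep & sel
  }
  if (!any(keep))
    return(structure(list(reason = "no valid samples"),
                     class = "no_valid_samples"))
  list(mean_velocity = mean(eye$velocity[keep]),
       mean_speed = mean(abs(eye$velocity[keep])),
       n_used = sum(keep))
}
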