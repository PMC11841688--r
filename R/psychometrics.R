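#' Bin trial responses by gain level
#'
#' Counts "with the head" responses per distinct gain for a single condition.
#'
#' @param trials Trial table (as from [simulate_trials()] or
#'   [read_trials()]) restricted to one condition; must be nonempty.
#' @return Object of class `binned_data`: a data frame with `gain`, `n_with`,
#'   `n_total`, sorted by gain.
#' @export
bin_responses <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L)
    stop_validation("no trials to bin")
  if (!is.null(trials$label) && length(unique(trials$label)) > 1L)
    stop_validation("trials mix conditions; bin one condition at a time")
  g <- factor(trials$gain, levels = sort(unique(trials$gain)))
  binned_data(as.numeric(levels(g)),
              as.integer(tapply(trials$response == "with", g, sum)),
              as.integer(table(g)))
}

#' @rdname bin_responses
#' @param gain,n_with,n_total Vectors defining the binned data directly.
#' @export
binned_data <- function(gain, n_with, n_total) {
  stopifnot(length(gain) == length(n_with), length(gain) == length(n_total))
  if (anyDuplicated(gain)) stop_validation("gains must be distinct")
  if (any(n_with < 0) || any(n_with > n_total))
    stop_validation("need 0 <= n_with <= n_total")
  drop <- n_total == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " gain level(s) with no trials")
    gain <- gain[!drop]; n_with <- n_with[!drop]; n_total <- n_total[!drop]
  }
  structure(data.frame(gain = gain, n_with = n_with, n_total = n_total),
            class = c("binned_data", "data.frame"))
}

# P("with" | gain) under the standard model
psy_prob <- function(gain, alpha, sigma, lapse = 0) {
  lapse + (1 - 2 * lapse) * stats::pnorm((gain - alpha) / sigma)
}

binom_loglik <- function(p, n_with, n_total) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(stats::dbinom(n_with, n_total, p, log = TRUE))
}

# probit-regression starting values (alpha, sigma)
probit_init <- function(data) {
  est <- tryCatch({
    fit <- suppressWarnings(stats::glm(
      cbind(n_with, n_total - n_with) ~ gain, data = data,
      family = stats::binomial(link = "probit")))
    b <- stats::coef(fit)
    if (is.finite(b[2]) && b[2] > 0) c(-b[1] / b[2], 1 / b[2]) else NULL
  }, error = function(e) NULL)
  if (is.null(est) || !all(is.finite(est)) || est[2] <= 0)
    est <- c(0, diff(range(data$gain)) / 4)
  est
}

run_mle <- function(starts, nll, lower, upper, gr = NULL, polish = TRUE) {
  results <- list()
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, nll, gr = gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value))
      results[[length(results) + 1L]] <- res
  }
  if (!length(results)) return(NULL)
  vals <- vapply(results, `[[`, numeric(1), "value")
  near <- which(vals <= min(vals) + 1e-6)
  # ties: prefer a converged run, then the smaller sigma
  conv <- vapply(results[near], function(r) r$convergence == 0, logical(1))
  if (any(conv)) near <- near[conv]
  sig <- vapply(results[near], function(r) r$par[2], numeric(1))
  best <- results[[near[which.min(sig)]]]
  if (polish) {
    # Nelder-Mead polish: L-BFGS-B line searches can abort on the
    # numerically flat likelihood near the optimum; the simplex step both
    # refines the solution and provides the honest convergence flag.
    clamp <- function(p) pmin(pmax(p, lower), upper)
    pol <- stats::optim(best$par, function(p) nll(clamp(p)),
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (pol$value <= best$value) {
      best$par <- clamp(pol$par)
      best$value <- pol$value
      best$convergence <- pol$convergence
    } else if (pol$convergence == 0) {
      best$convergence <- 0
    }
  }
  names(best$par) <- NULL
  best
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of
#' `P(with | g) = lambda + (1 - 2 lambda) * Phi((g - alpha)/sigma)` to binned
#' binomial data, with the lapse rate `lambda` a free parameter boxed to
#' `[0, lapse_max]`. The optimizer is bounded quasi-Newton (L-BFGS-B) over
#' `(alpha, log sigma, lambda)`, started at probit-regression values plus
#' four jittered restarts; ties are broken by higher log-likelihood, then
#' smaller `sigma`.
#'
#' @param data A [binned_data()] object with at least 3 gain levels.
#' @param lapse_max Upper bound on the lapse rate (default 0.02).
#' @param n_restarts Number of jittered restarts (default 4).
#' @param polish Run a Nelder-Mead polish after the quasi-Newton stage
#'   (default TRUE; the bootstrap turns it off for speed and relies on the
#'   analytic-gradient quasi-Newton convergence flag).
#' @return Object of class `psychfit`: `alpha` (PSE), `sigma` (SD, inverse
#'   slope), `lapse`, `loglik`, `converged`, `n_levels`. When every response
#'   is identical the fit is unidentifiable and an object of class
#'   `psychfit_unidentifiable` is returned instead.
#' @export
fit_cumulative_gaussian <- function(data, lapse_max = 0.02, n_restarts = 4,
                                    polish = TRUE) {
  stopifnot(inherits(data, "binned_data"))
  if (nrow(data) < 3L) stop_validation("need at least 3 gain levels")
  tot_with <- sum(data$n_with)
  if (tot_with == 0L || tot_with == sum(data$n_total)) {
    return(structure(
      list(reason = "all responses identical; PSE/slope unidentifiable",
           all_with = tot_with > 0L),
      class = "psychfit_unidentifiable"))
  }
  init <- probit_init(data)
  sig0 <- max(init[2], 1e-3)
  gr <- diff(range(data$gain))
  starts <- list(c(init[1], log(sig0), 0.005))
  if (n_restarts > 0) {
    for (k in seq_len(n_restarts)) {
      starts[[k + 1L]] <- c(
        init[1] + gr * c(-0.15, 0.15, 0, 0)[(k - 1L) %% 4L + 1L],
        log(sig0 * c(1, 1, 0.4, 2.5)[(k - 1L) %% 4L + 1L]),
        c(0.0, 0.01, 0.02, 0.005)[(k - 1L) %% 4L + 1L])
    }
  }
  nll <- function(par) {
    -binom_loglik(psy_prob(data$gain, par[1], exp(par[2]), par[3]),
                  data$n_with, data$n_total)
  }
  # analytic gradient wrt (alpha, log sigma, lapse)
  nll_grad <- function(par) {
    sigma <- exp(par[2]); lam <- par[3]
    z <- (data$gain - par[1]) / sigma
    Phi <- stats::pnorm(z); phi <- stats::dnorm(z)
    p <- pmin(pmax(lam + (1 - 2 * lam) * Phi, 1e-12), 1 - 1e-12)
    w <- data$n_with / p - (data$n_total - data$n_with) / (1 - p)
    -c(sum(w * (1 - 2 * lam) * phi * (-1 / sigma)),
       sum(w * (1 - 2 * lam) * phi * (-z)),
       sum(w * (1 - 2 * Phi)))
  }
  lower <- c(min(data$gain) - 2 * gr, log(1e-4), 0)
  upper <- c(max(data$gain) + 2 * gr, log(10), lapse_max)
  best <- run_mle(starts, nll, lower, upper, gr = nll_grad, polish = polish)
  if (is.null(best)) stop("psychometric fit failed from every start")
  structure(
    list(alpha = best$par[1], sigma = exp(best$par[2]), lapse = best$par[3],
         loglik = -best$value, converged = best$convergence == 0,
         n_levels = nrow(data)),
    class = "psychfit")
}

#' @export
print.psychfit <- function(x, ...) {
  cat(sprintf(
    "Cumulative-Gaussian fit: PSE = %.4f, sigma = %.4f, lapse = %.4f (logLik %.2f%s)\n",
    x$alpha, x$sigma, x$lapse, x$loglik,
    if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' Nonparametric bootstrap of a psychometric fit
#'
#' Resamples the Bernoulli outcomes within each gain level (binomial draws at
#' the empirical proportions, stratified by gain as the fixed design
#' dictates) and refits the psychometric function per replicate.
#' Non-converged or unidentifiable replicates are dropped and counted; a
#' warning flag is set in the result when more than 20% fail.
#'
#' @param data A [binned_data()] object.
#' @param n Number of bootstrap replicates (default 2000).
#' @param seed Optional integer seed.
#' @param lapse_max Lapse bound passed to the refits.
#' @return Object of class `bootstrap_result`: `samples` (data frame with
#'   `alpha`, `sigma`, `lapse` per retained replicate), `n_requested`,
#'   `n_retained`, `high_failure` flag.
#' @export
bootstrap_fit <- function(data, n = 2000, seed = NULL, lapse_max = 0.02) {
  stopifnot(inherits(data, "binned_data"))
  p_hat <- data$n_with / data$n_total
  with_seed(seed, {
    samples <- matrix(NA_real_, n, 3L,
                      dimnames = list(NULL, c("alpha", "sigma", "lapse")))
    ok <- logical(n)
    for (b in seq_len(n)) {
      res <- binned_data(data$gain,
                         stats::rbinom(nrow(data), data$n_total, p_hat),
                         data$n_total)
      fit <- tryCatch(
        fit_cumulative_gaussian(res, lapse_max = lapse_max, n_restarts = 1,
                                polish = FALSE),
        error = function(e) NULL)
      if (!is.null(fit) && inherits(fit, "psychfit") && fit$converged) {
        samples[b, ] <- c(fit$alpha, fit$sigma, fit$lapse)
        ok[b] <- TRUE
      }
    }
    fail_rate <- mean(!ok)
    if (fail_rate > 0.2)
      warning(sprintf("%.0f%% of bootstrap replicates failed", 100 * fail_rate))
    structure(
      list(samples = as.data.frame(samples[ok, , drop = FALSE]),
           n_requested = n, n_retained = sum(ok),
           high_failure = fail_rate > 0.2),
      class = "bootstrap_result")
  })
}

# quadrature nodes/weights for the truncated head-speed distribution
head_speed_quadrature <- function(mean, variance, floor = 15, n_nodes = 129) {
  sd <- sqrt(variance)
  if (sd == 0) return(list(h = mean, w = 1))
  lo <- max(floor, mean - 8 * sd)
  hi <- mean + 8 * sd
  h <- seq(lo, hi, length.out = n_nodes)
  w <- stats::dnorm(h, mean, sd)
  w[c(1, n_nodes)] <- w[c(1, n_nodes)] / 2       # trapezoid
  list(h = h, w = w / sum(w))
}

#' Psychometric curve marginalized over head-speed variability
#'
#' Judgments are coded as motion amplitude, so at fixed gain `g` a trial with
#' head speed `h` has success probability `Phi((g - g0) h / sigma_amp)`.
#' Across trials `h` varies, and the observed proportion is the expectation
#' over the (floor-truncated) Gaussian head-speed distribution, evaluated by
#' fixed-grid trapezoid quadrature on `n_nodes` (>= 64) nodes.
#'
#' @param gains Gain values at which to evaluate the curve.
#' @param g0 Bias (PSE-like), gain units.
#' @param sigma_amp Amplitude noise SD, deg/s.
#' @param head_dist A [fit_velocity_distribution()] object (or list with
#'   `mean`, `variance` in deg/s).
#' @param lapse Lapse rate.
#' @param floor Head-speed truncation floor, deg/s (default 15).
#' @param n_nodes Quadrature nodes (default 129).
#' @return Predicted proportions "with", same length as `gains`.
#' @export
across_trial_curve <- function(gains, g0, sigma_amp, head_dist, lapse = 0,
                               floor = 15, n_nodes = 129) {
  q <- head_speed_quadrature(head_dist$mean, head_dist$variance,
                             floor = floor, n_nodes = n_nodes)
  inner <- vapply(gains, function(g)
    sum(q$w * stats::pnorm((g - g0) * q$h / sigma_amp)), numeric(1))
  lapse + (1 - 2 * lapse) * inner
}

#' Fit the across-trial-noise psychometric model
#'
#' Maximum-likelihood fit of the head-speed-marginalized psychometric model
#' (see [across_trial_curve()]): free parameters are the bias `g0` (gain
#' units), the amplitude noise SD `sigma_amp` (deg/s), and the lapse rate.
#' The head-speed distribution is measured, not fitted. At zero head-speed
#' variance the model reduces exactly to the standard cumulative Gaussian
#' with `sigma = sigma_amp / mean`.
#'
#' @param data A [binned_data()] object.
#' @param head_dist A [fit_velocity_distribution()] result with `mean > 0`.
#' @param lapse_max Lapse bound (default 0.02).
#' @param floor,n_nodes Passed to [across_trial_curve()].
#' @return Object of class `across_trial_fit`: `g0`, `sigma_amp`, `lapse`,
#'   `head_dist`, `loglik`, `converged`.
#' @export
fit_across_trial_model <- function(data, head_dist, lapse_max = 0.02,
                                   floor = 15, n_nodes = 129) {
  stopifnot(inherits(data, "binned_data"))
  if (head_dist$variance < 0) stop_validation("head variance must be >= 0")
  if (!(head_dist$mean > 0)) stop_validation("head mean speed must be > 0")
  q <- head_speed_quadrature(head_dist$mean, head_dist$variance,
                             floor = floor, n_nodes = n_nodes)
  nll <- function(par) {
    inner <- vapply(data$gain, function(g)
      sum(q$w * stats::pnorm((g - par[1]) * q$h / exp(par[2]))), numeric(1))
    -binom_loglik(par[3] + (1 - 2 * par[3]) * inner,
                  data$n_with, data$n_total)
  }
  std <- fit_cumulative_gaussian(data, lapse_max = lapse_max)
  if (inherits(std, "psychfit_unidentifiable"))
    stop_validation("responses all identical; model unidentifiable")
  s0 <- std$sigma * head_dist$mean
  gr <- diff(range(data$gain))
  starts <- list(c(std$alpha, log(s0), std$lapse),
                 c(std$alpha, log(s0 * 0.5), 0.005),
                 c(std$alpha, log(s0 * 2), 0.01))
  best <- run_mle(starts, nll,
                  lower = c(min(data$gain) - 2 * gr, log(1e-3), 0),
                  upper = c(max(data$gain) + 2 * gr, log(1e4), lapse_max))
  if (is.null(best)) stop("across-trial fit failed from every start")
  structure(
    list(g0 = best$par[1], sigma_amp = exp(best$par[2]), lapse = best$par[3],
         head_dist = head_dist, loglik = -best$value,
         converged = best$convergence == 0),
    class = "across_trial_fit")
}

#' @export
print.across_trial_fit <- function(x, ...) {
  cat(sprintf(
    "Across-trial-noise fit: g0 = %.4f, sigma_amp = %.3f deg/s, lapse = %.4f (logLik %.2f)\n",
    x$g0, x$sigma_amp, x$lapse, x$loglik))
  invisible(x)
}

#' Model-implied psychometric curve
#'
#' Evaluates a fitted (or predicted) model's `P(with | gain)` at the given
#' gains. Methods exist for `psychfit`, `across_trial_fit`, and plain
#' parameter lists with `alpha`/`sigma` (optionally `lapse`).
#'
#' @param fit A fit object or parameter list.
#' @param gains Gain values.
#' @param ... Passed to methods.
#' @return Predicted proportions, bounded by the lapse asymptotes.
#' @export
model_implied_curve <- function(fit, gains, ...) UseMethod("model_implied_curve")

#' @export
model_implied_curve.psychfit <- function(fit, gains, ...) {
  psy_prob(gains, fit$alpha, fit$sigma, fit$lapse)
}

#' @export
model_implied_curve.across_trial_fit <- function(fit, gains, ...) {
  across_trial_curve(gains, fit$g0, fit$sigma_amp, fit$head_dist, fit$lapse)
}

#' @export
model_implied_curve.default <- function(fit, gains, ...) {
  lapse <- if (is.null(fit$lapse)) 0 else fit$lapse
  if (!is.null(fit$alpha) && !is.null(fit$sigma))
    return(psy_prob(gains, fit$alpha, fit$sigma, lapse))
  stop_validation("cannot evaluate a curve for this object")
}

#' Root-mean-square error between two proportion vectors
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop_validation("predicted and observed must have equal length")
  sqrt(mean((predicted - observed)^2))
}
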