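# Log-Gaussian temporal response model and per-cell feature extraction.
#
# Each cell's post-offset excitatory response is modelled as
#   r(t) = baseline + A exp(-((ln t - mu) / sigma)^2)
# i.e. Gaussian in log time. Closed-form features:
#   peak time   = exp(mu)
#   half-width  = 2 exp(mu) sinh(sigma sqrt(ln 2))
#   half-decay  = exp(mu) (exp(sigma sqrt(ln 2)) - 1)
#   half-width / peak-time = 2 sinh(sigma sqrt(ln 2))  (mu-free: constant
#   log-width implies a constant ratio across the whole continuum).

#' Evaluate the log-Gaussian response curve
#'
#' @param t times, s (values at t <= 0 are 0).
#' @param A amplitude above baseline, Hz.
#' @param mu log peak location, ln s.
#' @param sigma log-time width (dimensionless).
#' @param baseline baseline rate, Hz.
#' @return rate values, Hz.
#' @export
log_gaussian <- function(t, A, mu, sigma, baseline = 0) {
  out <- rep(baseline, length(t))
  on <- t > 0
  out[on] <- baseline + A * exp(-((log(t[on]) - mu) / sigma)^2)
  out
}

#' Adjusted R-squared
#'
#' \deqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - p - 1).}
#' Can be negative for poor fits.
#'
#' @param r2 unadjusted R-squared.
#' @param n_samples sample size.
#' @param n_params number of model parameters.
#' @return adjusted R-squared.
#' @examples
#' adjusted_r2(0.5, 12, 1)  # 0.45
#' @export
adjusted_r2 <- function(r2, n_samples, n_params) {
  if (n_samples <= n_params + 1)
    stop("n_samples must exceed n_params + 1")
  1 - (1 - r2) * (n_samples - 1) / (n_samples - n_params - 1)
}

#' Fit the log-Gaussian response model
#'
#' Bounded nonlinear fit of \code{A exp(-((ln t - mu)/sigma)^2)} to a cell's
#' post-offset response, in one of two modes.
#'
#' \strong{Trace mode} (no \code{trains}): least squares of the model
#' against the baseline-subtracted rate on the trace's log-spaced samples
#' (every decade weighted equally). Appropriate for noiseless model traces
#' and externally supplied smooth rates.
#'
#' \strong{Count mode} (\code{trains} supplied): the reciprocal-ISI rate
#' estimate has infinite pointwise variance (the interval covering a fixed
#' time is length-biased, so E[1/ISI^2] diverges), which destabilizes plain
#' least squares on fine grids. Spike counts in log-spaced bins are
#' well-behaved, so the fit minimizes the Poisson deviance of binned counts
#' against the model \code{baseline_fit + A exp(...)} — equivalent to
#' iteratively reweighted (inverse-variance) least squares — with the
#' absolute refractory dead-time in the forward model
#' (\code{rate/(1 + rate*refractory)}) and the fitted baseline constrained
#' near the measured pre-onset baseline. Multi-start over initial peak
#' locations and widths; the best deviance wins.
#'
#' For cells with an identified firing pause, samples at
#' \code{t <= mask_below} are censored: there the observed rate is floored
#' at zero by mGluR2/3 suppression while the model describes the
#' mGluR1-driven excitatory component.
#'
#' @param trace a (trial-averaged) \code{rate_trace}.
#' @param baseline a \code{baseline_stats} object.
#' @param mask_below censor samples at t <= this value, s (NULL = none).
#' @param bounds_sigma,bounds_mu parameter bounds.
#' @param trains optional \code{spike_trains} enabling count mode.
#' @param refractory absolute refractory period used in count mode, s.
#' @param t_max_fit last time entering the count-mode fit, s (defaults to
#'   the span of the spike trains, capped at 100 s).
#' @param n_bins log-spaced count bins.
#' @return object of class \code{log_gaussian_fit}: coefficients \code{A},
#'   \code{mu}, \code{sigma}, plus \code{baseline} (measured),
#'   \code{baseline_fit} (count mode), \code{r2_adj}, \code{converged},
#'   \code{not_applicable} (pure suppression), \code{at_bounds}, and the
#'   fitted data.
#' @export
fit_log_gaussian <- function(trace, baseline, mask_below = NULL,
                             bounds_sigma = c(0.1, 5),
                             bounds_mu = log(c(0.005, 60)),
                             trains = NULL, refractory = 0.002,
                             t_max_fit = NULL, n_bins = 80) {
  sel <- trace$time > 0
  if (!is.null(mask_below)) sel <- sel & trace$time > mask_below
  t <- trace$time[sel]
  y <- trace$rate[sel] - baseline$mean_hz
  if (!length(t)) stop("trace has no usable post-offset samples")

  blank <- function(A, converged, na) {
    structure(list(A = A, mu = NA_real_, sigma = NA_real_,
                   baseline = baseline$mean_hz, baseline_fit = NA_real_,
                   r2_adj = NA_real_, converged = converged,
                   not_applicable = na, at_bounds = FALSE),
              class = "log_gaussian_fit")
  }
  if (max(trace$rate[sel]) <= 0) return(blank(0, TRUE, TRUE))

  if (is.null(trains)) {
    # ---- trace mode: plain least squares on the log-spaced samples ----
    if (max(y) <= 0.5 * baseline$sd_hz) return(blank(0, TRUE, TRUE))
    lt <- log(t)
    ys <- if (length(y) > 9) stats::runmed(y, 9) else y
    mu0 <- min(max(lt[which.max(ys)], bounds_mu[1]), bounds_mu[2])
    A0 <- max(max(ys), 1)
    one_fit <- function(sigma0) {
      df <- data.frame(lt = lt, y = y)
      tryCatch(
        minpack.lm::nlsLM(y ~ A * exp(-((lt - mu) / sigma)^2), data = df,
                          start = list(A = A0, mu = mu0, sigma = sigma0),
                          lower = c(0, bounds_mu[1], bounds_sigma[1]),
                          upper = c(Inf, bounds_mu[2], bounds_sigma[2]),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    }
    m <- one_fit(1)
    if (is.null(m)) m <- one_fit(2)
    if (is.null(m)) return(blank(NA_real_, FALSE, FALSE))
    cf <- stats::coef(m)
    r2 <- 1 - sum(stats::resid(m)^2) / sum((y - mean(y))^2)
    cf <- c(cf, b = 0)
    pred <- NULL
    n_fit <- length(y)
  } else {
    # ---- count mode: Poisson deviance on log-binned spike counts ----
    n_trials <- attr(trains, "n_trials")
    if (is.null(n_trials)) n_trials <- max(trains$trial)
    t_lo <- if (!is.null(mask_below)) max(mask_below, 1e-3) else
      max(min(t), 1e-3)
    if (is.null(t_max_fit)) t_max_fit <- min(max(trains$time, max(t)), 100)
    br <- exp(seq(log(t_lo), log(t_max_fit), length.out = n_bins + 1))
    cnt <- tabulate(findInterval(
      trains$time[trains$time > t_lo & trains$time <= t_max_fit],
      br, rightmost.closed = TRUE), n_bins)
    ltc <- log(sqrt(br[-1] * br[-(n_bins + 1)]))
    tw <- diff(br)
    blm <- min(baseline$mean_hz, 0.9 / refractory)
    blm <- blm / (1 - blm * refractory)   # dead-time-corrected baseline
    # expected counts integrate the dead-time-compressed model over each
    # bin (Simpson's rule): bin-center evaluation alone biases the fit
    # where the curve is strongly convex or concave
    lt_a <- log(br[-(n_bins + 1)]); lt_b <- log(br[-1])
    lt_m <- log((br[-(n_bins + 1)] + br[-1]) / 2)
    lamf <- function(p) {
      g <- function(lt) {
        r <- p[4] + p[1] * exp(-((lt - p[2]) / p[3])^2)
        r / (1 + r * refractory)
      }
      pmax(n_trials * tw * (g(lt_a) + 4 * g(lt_m) + g(lt_b)) / 6, 1e-9)
    }
    obj <- function(p) {
      l <- lamf(p)
      2 * sum(ifelse(cnt > 0, cnt * log(cnt / l), 0) - (cnt - l))
    }
    lo <- c(0, bounds_mu[1], bounds_sigma[1], max(0, 0.8 * blm - 0.5))
    hi <- c(2e3, bounds_mu[2], bounds_sigma[2], 1.2 * blm + 0.5)
    rate_bin <- cnt / tw / n_trials
    A0 <- max(max(rate_bin) - blm, 1)
    mu0s <- unique(c(ltc[order(-rate_bin)][1:2], log(0.3), log(1.5)))
    best <- NULL
    for (mu0 in mu0s) for (s0 in c(1, 1.8, 3)) {
      p0 <- pmin(pmax(c(A0, mu0, s0, blm), lo + 1e-6), hi - 1e-6)
      op <- tryCatch(stats::optim(p0, obj, method = "L-BFGS-B", lower = lo,
                                  upper = hi, control = list(maxit = 500)),
                     error = function(e) NULL)
      if (is.null(op)) next
      op2 <- stats::optim(op$par, function(p)
        if (any(p < lo) || any(p > hi)) 1e10 else obj(p),
        method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-10))
      if (op2$value < op$value) op <- op2
      if (is.null(best) || op$value < best$value) best <- op
    }
    if (is.null(best)) return(blank(NA_real_, FALSE, FALSE))
    cf <- stats::setNames(best$par, c("A", "mu", "sigma", "b"))
    # parameter standard errors from the deviance curvature (observed
    # Fisher information): se_A judges whether an excitatory component is
    # present; se_sigma feeds the population-level width pooling
    ses <- tryCatch({
      H <- stats::optimHess(best$par, obj) / 2
      sqrt(pmax(diag(solve(H)), 0))
    }, error = function(e) rep(NA_real_, 4))
    se_A <- ses[1]; se_sigma <- ses[3]
    pred <- cf[["b"]] + cf[["A"]] * exp(-((ltc - cf[["mu"]]) / cf[["sigma"]])^2)
    # R^2 on binned rates, with the model dead-time-compressed like the data
    r2 <- 1 - sum((rate_bin - pred / (1 + pred * refractory))^2) /
      sum((rate_bin - mean(rate_bin))^2)
    n_fit <- n_bins
    t <- exp(ltc)
    y <- rate_bin - blm
  }

  # a width narrower than ~3 count bins is unresolved: such "fits" are
  # single noise bumps, not temporal responses
  sigma_floor <- if (is.null(trains)) bounds_sigma[1] + 1e-6 else
    max(bounds_sigma[1] + 1e-6, 3 * (log(t_max_fit) - log(t_lo)) / n_bins)
  at_bounds <- cf[["sigma"]] <= sigma_floor ||
    cf[["sigma"]] >= bounds_sigma[2] - 1e-6
  fit <- list(A = unname(cf[["A"]]), mu = unname(cf[["mu"]]),
              sigma = unname(cf[["sigma"]]), baseline = baseline$mean_hz,
              baseline_fit = if (is.null(trains)) baseline$mean_hz
                             else unname(cf[["b"]]),
              se_A = if (is.null(trains)) NA_real_ else se_A,
              se_sigma = if (is.null(trains)) NA_real_ else se_sigma,
              r2_adj = adjusted_r2(r2, n_fit, 3),
              converged = TRUE, not_applicable = FALSE,
              at_bounds = at_bounds, t = t, y = y)
  class(fit) <- "log_gaussian_fit"
  fit
}

#' @export
print.log_gaussian_fit <- function(x, ...) {
  if (x$not_applicable) {
    cat("log-Gaussian fit: not applicable (pure suppression, A = 0)\n")
  } else if (!x$converged) {
    cat("log-Gaussian fit: did not converge\n")
  } else {
    cat(sprintf(paste0("log-Gaussian fit: A = %.1f Hz, mu = %.3f (peak %.3g s),",
                       " sigma = %.3f, adj. R^2 = %.3f%s\n"),
                x$A, x$mu, exp(x$mu), x$sigma, x$r2_adj,
                if (x$at_bounds) " [sigma at bound]" else ""))
  }
  invisible(x)
}

#' @export
coef.log_gaussian_fit <- function(object, ...) {
  c(A = object$A, mu = object$mu, sigma = object$sigma)
}

#' @export
predict.log_gaussian_fit <- function(object, t, ...) {
  if (object$not_applicable) return(rep(object$baseline, length(t)))
  log_gaussian(t, object$A, object$mu, object$sigma, object$baseline)
}

#' @export
residuals.log_gaussian_fit <- function(object, ...) {
  if (is.null(object$t)) return(numeric(0))
  object$y - (predict(object, object$t) - object$baseline)
}

#' Closed-form response features from a fitted log-Gaussian
#'
#' @param fit a \code{log_gaussian_fit}.
#' @param pause measured pause duration, s (0 or NA when none).
#' @return list of class \code{response_features}: \code{peak_time},
#'   \code{half_width}, \code{half_decay} (all s), \code{amplitude} (Hz),
#'   \code{hw_pt_ratio}, \code{pause}, \code{baseline},
#'   \code{low_confidence} (sigma at a fit bound).
#' @export
features_from_fit <- function(fit, pause = 0) {
  if (fit$not_applicable || !fit$converged) {
    return(structure(list(peak_time = NA_real_, half_width = NA_real_,
                          half_decay = NA_real_, amplitude = fit$A,
                          hw_pt_ratio = NA_real_,
                          pause = if (is.na(pause)) 0 else pause,
                          baseline = fit$baseline,
                          low_confidence = !fit$converged),
                     class = "response_features"))
  }
  s <- fit$sigma * SQRT_LN2
  structure(list(peak_time = exp(fit$mu),
                 half_width = 2 * exp(fit$mu) * sinh(s),
                 half_decay = exp(fit$mu) * (exp(s) - 1),
                 amplitude = fit$A,
                 hw_pt_ratio = 2 * sinh(s),
                 pause = if (is.na(pause)) 0 else pause,
                 baseline = fit$baseline,
                 amp_significant = is.na(fit$se_A) ||
                   fit$A > 2 * fit$se_A,
                 low_confidence = fit$at_bounds),
            class = "response_features")
}

#' @export
print.response_features <- function(x, ...) {
  cat(sprintf(paste0("response features: peak %.3g s, half-width %.3g s ",
                     "(ratio %.2f), half-decay %.3g s, amplitude %.1f Hz, ",
                     "pause %.3g s\n"),
              x$peak_time, x$half_width, x$hw_pt_ratio, x$half_decay,
              x$amplitude, x$pause))
  invisible(x)
}

#' Empirical-Bayes pooling of log-Gaussian widths across a population
#'
#' The temporal-basis model holds that all cells share a common log-time
#' width up to small cell-to-cell variation, while per-cell width estimates
#' from a handful of trials carry substantial sampling error. Random-effects
#' pooling is the standard estimator for this setting: the between-cell
#' variance tau^2 is estimated by DerSimonian-Laird moments from the
#' per-cell estimates and their standard errors, and each cell's width is
#' shrunk toward the precision-weighted population mean,
#' \deqn{\sigma_i^* = (\tau^2 \hat\sigma_i + s_i^2 \bar\sigma) /
#'   (\tau^2 + s_i^2).}
#'
#' @param sigma per-cell width estimates.
#' @param se their standard errors (from the fit's Fisher information).
#' @return list: \code{mean} (precision-weighted population mean),
#'   \code{tau} (between-cell SD), \code{shrunk} (per-cell pooled widths).
#' @export
pool_log_widths <- function(sigma, se) {
  ok <- is.finite(sigma) & is.finite(se) & se > 0
  if (sum(ok) < 3)
    return(list(mean = mean(sigma[is.finite(sigma)]), tau = NA_real_,
                shrunk = sigma))
  w <- 1 / se[ok]^2
  m_fixed <- sum(w * sigma[ok]) / sum(w)
  q <- sum(w * (sigma[ok] - m_fixed)^2)
  k <- sum(ok)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  # the shrink target is a trimmed unweighted mean: the fitted standard
  # error scales with the fitted width, so precision weighting would
  # overweight cells that underestimate the width
  m <- mean(sigma[ok], trim = 0.1)
  shrunk <- sigma
  shrunk[ok] <- (tau2 * sigma[ok] + se[ok]^2 * m) / (tau2 + se[ok]^2)
  list(mean = m, tau = sqrt(tau2), shrunk = shrunk)
}

#' Classify a cell's response profile
#'
#' Operational classification mirroring the excited / biphasic / suppressed
#' partition: the excitation criterion is a fitted amplitude of at least
#' \code{max(min_amp_hz, amp_baseline_frac * baseline)} from a trustworthy
#' fit; the pause criterion is a measured pause of at least
#' \code{pause_isi_mult} baseline inter-spike intervals (a pause
#' distinguishable from ordinary ISI variability). Cells meeting only the
#' excitation criterion are \code{excited}, both \code{biphasic}, only the
#' pause criterion \code{suppressed}, neither \code{unresponsive}.
#'
#' @param features a \code{response_features}.
#' @param baseline a \code{baseline_stats}.
#' @param min_amp_hz absolute amplitude floor, Hz.
#' @param amp_baseline_frac relative amplitude floor.
#' @param pause_isi_mult pause threshold in baseline ISIs.
#' @return one of \code{"excited"}, \code{"biphasic"}, \code{"suppressed"},
#'   \code{"unresponsive"}.
#' @export
classify_response <- function(features, baseline, min_amp_hz = 5,
                              amp_baseline_frac = 0.2, pause_isi_mult = 3) {
  amp_ok <- !is.na(features$amplitude) && !isTRUE(features$low_confidence) &&
    !isFALSE(features$amp_significant) &&
    features$amplitude >= max(min_amp_hz,
                              amp_baseline_frac * baseline$mean_hz)
  pause_ok <- !is.na(baseline$mean_isi_s) && !is.na(features$pause) &&
    features$pause >= pause_isi_mult * baseline$mean_isi_s
  if (amp_ok && pause_ok) "biphasic"
  else if (amp_ok) "excited"
  else if (pause_ok) "suppressed"
  else "unresponsive"
}
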