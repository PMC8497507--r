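# Population generator: latent continuum -> per-cell parameters.
#
# The UBC population is modelled as a one-dimensional continuum. Excitatory
# response peak times are log-uniform over two orders of magnitude; the
# log-time response width sigma is constant up to jitter; amplitude trades
# off against duration (soft minimum of a ~200 Hz saturation plateau and a
# 1/peak-time conservation line); the slower excitatory cells carry an
# mGluR2/3 pause before excitation (biphasic), and a purely suppressed (OFF)
# group fires spontaneously at high rates.

SQRT_LN2 <- sqrt(log(2))

#' Calibrate the supra-linear f-I exponent
#'
#' The firing rate is modelled as baseline + k * I^p for net inward current
#' I >= 0. A log-Gaussian current of log-width \code{sigma_I} then maps onto a
#' log-Gaussian rate of width \code{sigma_I / sqrt(p)}, so the ratio of
#' current to rate half-decay times is
#' \deqn{(e^{\sigma\sqrt{p\ln 2}} - 1) / (e^{\sigma\sqrt{\ln 2}} - 1)}
#' with \code{sigma} the rate log-width. This solves for the exponent p that
#' yields a target half-decay ratio (the observed population value is 2.0).
#'
#' @param sigma0 rate log-width (dimensionless).
#' @param target_ratio desired current/rate half-decay ratio.
#' @return the f-I exponent p (> 1 for ratios > 1).
#' @examples
#' calibrate_fi_exponent(1.787, 2)  # ~1.92
#' @export
calibrate_fi_exponent <- function(sigma0 = 1.787, target_ratio = 2) {
  stopifnot(sigma0 > 0, target_ratio > 0)
  s <- sigma0 * SQRT_LN2
  sig_i <- log(target_ratio * (exp(s) - 1) + 1) / SQRT_LN2
  (sig_i / sigma0)^2
}

#' Amplitude-duration tradeoff law
#'
#' Soft minimum of the saturation plateau \code{amp_sat} and the
#' spike-count-conserving line \code{amp_sat * knee / t_peak}:
#' \deqn{A(t) = A_{sat} (1 + (t/t_c)^s)^{-1/s}.}
#' On a log-log plot this is an inverted-soft-plus-shaped curve: flat near
#' \code{amp_sat} for fast cells, decaying as 1/t for slow cells, so the
#' product amplitude x duration (hence the evoked spike count) is
#' approximately constant away from the plateau.
#'
#' @param t_peak response peak time, s.
#' @param amp_sat saturation amplitude, Hz.
#' @param knee peak time at which saturation gives way to conservation, s.
#' @param sharpness soft-min exponent s (larger = sharper knee).
#' @return amplitude above baseline, Hz.
#' @export
amplitude_law <- function(t_peak, amp_sat = 200, knee = 0.07, sharpness = 2) {
  amp_sat * (1 + (t_peak / knee)^sharpness)^(-1 / sharpness)
}

#' Continuum generator parameters
#'
#' Bundles the distributional parameters of the synthetic UBC population.
#' Defaults reproduce the reference study conditions: 84 cells split
#' 28 pure-ON / 42 biphasic / 14 OFF; excitatory log10 peak times uniform on
#' [-1.50, 0.363] (0.032 s to 2.3 s); constant log-width sigma0 = 1.787
#' (the width whose half-width/peak-time ratio is 4.2); amplitudes saturating
#' near 200 Hz with a 1/t conservation tail; pauses resolvable against each
#' pausing cell's own baseline inter-spike interval.
#'
#' @param n_cells total cells.
#' @param n_pure_on,n_biphasic,n_off class composition; must sum to
#'   \code{n_cells}.
#' @param log10_peak_time_range range of log10 peak time (s) for excitatory
#'   cells.
#' @param sigma0 log-time response width (dimensionless).
#' @param sigma_jitter SD of per-cell jitter added to \code{sigma0}.
#' @param amp_saturation amplitude plateau, Hz.
#' @param amp_knee peak time of the amplitude-law knee, s.
#' @param amp_sharpness soft-min exponent of the amplitude law.
#' @param amp_jitter per-cell lognormal amplitude scatter, dex.
#' @param pause_peak_ratio biphasic pause duration as a fraction of the
#'   cell's peak time (pauses are briefer in faster cells).
#' @param pause_floor minimum biphasic pause duration, s (shorter pauses
#'   would be unresolvable against the baseline inter-spike interval).
#' @param log10_off_pause_range range of log10 pause (s) for OFF cells.
#' @param pause_max upper cap on pause duration, s.
#' @param baseline_pure_on,baseline_off Uniform(lo, hi) baseline-rate ranges,
#'   Hz.
#' @param biphasic_baseline_factor Uniform(lo, hi) multiplier on 5/pause
#'   giving biphasic baseline rates (keeps the pause longer than ~5
#'   inter-spike intervals, hence detectable).
#' @param baseline_floor,baseline_cap clamps on biphasic baselines, Hz.
#' @param fi_exponent supra-linear f-I exponent p (> 1); default calibrated
#'   so the current outlasts the rate by a factor of 2 in half-decay.
#' @param fi_gain f-I gain k in Hz/pA^p; default maps a 100 pA inward peak
#'   to \code{amp_saturation}.
#' @param fast_charge_frac fraction of total excitatory charge carried by the
#'   fast ionotropic component (complement of the mGluR1 share).
#' @param tau_rise_s rise time constant of the outward mGluR2/3 component, s.
#' @param tau_fast_s decay time constant of the fast ionotropic component, s.
#' @param seed optional integer seed stored with the parameters.
#' @return an object of class \code{continuum_params}.
#' @export
continuum_params <- function(n_cells = 84,
                             n_pure_on = 28, n_biphasic = 42, n_off = 14,
                             log10_peak_time_range = c(-1.50, 0.363),
                             sigma0 = 1.787, sigma_jitter = 0.05,
                             amp_saturation = 200, amp_knee = 0.09,
                             amp_sharpness = 2, amp_jitter = 0.03,
                             pause_peak_ratio = 0.19,
                             pause_floor = 0.085,
                             log10_off_pause_range = c(log10(0.4), 0.021),
                             pause_max = 10^0.021,
                             baseline_pure_on = c(0, 15),
                             baseline_off = c(20, 60),
                             biphasic_baseline_factor = c(1.1, 1.6),
                             baseline_floor = 8, baseline_cap = 65,
                             fi_exponent = calibrate_fi_exponent(sigma0, 2),
                             fi_gain = amp_saturation / 100^fi_exponent,
                             fast_charge_frac = 0.09,
                             tau_rise_s = 0.05, tau_fast_s = 0.005,
                             seed = NULL) {
  if (n_pure_on + n_biphasic + n_off != n_cells)
    stop("class counts (", n_pure_on, " + ", n_biphasic, " + ", n_off,
         ") must sum to n_cells (", n_cells, ")")
  stopifnot(diff(log10_peak_time_range) > 0, sigma0 > 0, fi_exponent > 1,
            fi_gain > 0, fast_charge_frac >= 0, fast_charge_frac < 1)
  if (n_off > 0 && n_off < n_cells)
    stopifnot(diff(log10_off_pause_range) > 0)
  obj <- as.list(environment())
  class(obj) <- "continuum_params"
  obj
}

#' @export
print.continuum_params <- function(x, ...) {
  cat(sprintf(paste0("UBC continuum parameters: %d cells ",
                     "(%d pure-ON / %d biphasic / %d OFF)\n"),
              x$n_cells, x$n_pure_on, x$n_biphasic, x$n_off))
  cat(sprintf("  log10 peak time in [%.3f, %.3f], sigma0 = %.3f (+/- %.2f)\n",
              x$log10_peak_time_range[1], x$log10_peak_time_range[2],
              x$sigma0, x$sigma_jitter))
  cat(sprintf("  amplitude saturation %g Hz (knee %g s), f-I exponent %.3f\n",
              x$amp_saturation, x$amp_knee, x$fi_exponent))
  invisible(x)
}

#' Sample a synthetic UBC population
#'
#' Draws per-cell parameters from the continuum: excitatory peak times
#' log-uniform over the configured range; the fastest \code{n_pure_on}
#' excitatory cells are pure-ON, the slower \code{n_biphasic} carry a pause
#' (pauses are briefer in cells with shorter-lived excitation); OFF cells
#' have no excitatory component, high spontaneous rates and the longest
#' pauses. Current-side parameters (inward/outward amplitudes, widths, time
#' constants) are filled by \code{\link{derive_current_params}}.
#'
#' @param params a \code{\link{continuum_params}} object.
#' @param protocol a \code{\link{stimulus_protocol}}; needed to size the
#'   outward-current time course (its rise spans the stimulus burst).
#' @param seed integer seed; overrides \code{params$seed}.
#' @return a data.frame of class \code{ubc_population}, one row per cell.
#' @examples
#' pop <- sample_population(continuum_params(), seed = 1)
#' table(pop$class)
#' @export
sample_population <- function(params = continuum_params(),
                              protocol = stimulus_protocol(),
                              seed = NULL) {
  seed <- if (!is.null(seed)) seed else params$seed
  if (!is.null(seed)) set.seed(seed)
  n_exc <- params$n_pure_on + params$n_biphasic

  lo <- params$log10_peak_time_range[1]
  hi <- params$log10_peak_time_range[2]
  # stratified log-uniform draw (one uniform per equal log-width stratum):
  # marginally Uniform(lo, hi) in log10, but reproduces the tight uniform
  # progression of peak times the population shows
  peak <- 10^(lo + (seq_len(n_exc) - stats::runif(n_exc)) / n_exc * (hi - lo))
  cls <- c(rep("pure_on", params$n_pure_on), rep("biphasic", params$n_biphasic))

  sigma_r <- params$sigma0 + stats::rnorm(n_exc, 0, params$sigma_jitter)
  sigma_r <- pmax(sigma_r, 0.2)
  amp <- amplitude_law(peak, params$amp_saturation, params$amp_knee,
                       params$amp_sharpness) *
    10^stats::rnorm(n_exc, 0, params$amp_jitter)
  amp <- pmin(amp, params$amp_saturation)

  pause <- numeric(n_exc)
  is_bi <- cls == "biphasic"
  pause[is_bi] <- pmin(pmax(params$pause_peak_ratio * peak[is_bi],
                            params$pause_floor), params$pause_max)

  baseline <- numeric(n_exc)
  baseline[!is_bi] <- stats::runif(sum(!is_bi), params$baseline_pure_on[1],
                                   params$baseline_pure_on[2])
  fac <- stats::runif(sum(is_bi), params$biphasic_baseline_factor[1],
                      params$biphasic_baseline_factor[2])
  baseline[is_bi] <- pmin(pmax(5 / pause[is_bi] * fac, params$baseline_floor),
                          params$baseline_cap)

  exc <- data.frame(cell_id = seq_len(n_exc), class = cls,
                    baseline_hz = baseline, amp_hz = amp,
                    peak_time_s = peak, mu_r = log(peak), sigma_r = sigma_r,
                    pause_s = pause, stringsAsFactors = FALSE)

  if (params$n_off > 0) {
    off_pause <- sort(10^stats::runif(params$n_off,
                                      params$log10_off_pause_range[1],
                                      params$log10_off_pause_range[2]))
    off <- data.frame(cell_id = n_exc + seq_len(params$n_off), class = "off",
                      baseline_hz = stats::runif(params$n_off,
                                                 params$baseline_off[1],
                                                 params$baseline_off[2]),
                      amp_hz = 0, peak_time_s = NA_real_, mu_r = NA_real_,
                      sigma_r = NA_real_, pause_s = off_pause,
                      stringsAsFactors = FALSE)
    pop <- rbind(exc, off)
  } else pop <- exc

  pop$dgk_scale <- 1
  pop <- derive_current_params(pop, p = params$fi_exponent,
                               k = params$fi_gain, protocol = protocol,
                               params = params)
  attr(pop, "params") <- params
  attr(pop, "protocol") <- protocol
  class(pop) <- c("ubc_population", "data.frame")
  pop
}
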