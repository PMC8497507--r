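#' Supra-linear f-I transform
#'
#' Maps a synaptic current trace to an instantaneous firing-rate trace:
#' \deqn{r(t) = r_b + k I(t)^p \quad (I \ge 0)}
#' \deqn{r(t) = r_b \max(0,\; 1 + I(t)/I_0) \quad (I < 0)}
#' The supra-linearity (p > 1) temporally sharpens the spiking response
#' relative to the current: a log-Gaussian current of log-width sigma_I maps
#' onto a log-Gaussian rate of width sigma_I/sqrt(p), so the current outlasts
#' the rate. Net outward current suppresses firing linearly down to zero at
#' the suppression scale I_0; by default I_0 is calibrated per cell as the
#' magnitude of the net current at the cell's pause end, so the simulated
#' pause matches the drawn pause duration.
#'
#' @param current a \code{\link{synth_current}} trace.
#' @param cell the matching \code{ubc_population} row (baseline, pause).
#' @param p f-I exponent (> 1).
#' @param k f-I gain, Hz/pA^p.
#' @param i0 suppression scale, pA; \code{NULL} = calibrate from the pause.
#' @param rate_cap hard ceiling on the instantaneous rate, Hz: the power law
#'   extrapolated to the large but brief ionotropic transients during the
#'   stimulus burst would otherwise predict unphysiological rates.
#' @return an object of class \code{rate_trace}: list with \code{time},
#'   \code{rate} (Hz, finite and >= 0), \code{cell_id}, \code{n_trials}.
#' @export
f_i_transform <- function(current, cell, p, k, i0 = NULL, rate_cap = 500) {
  stopifnot(p > 1, k > 0)
  I <- current$total
  rb <- cell$baseline_hz
  if (is.null(i0)) {
    pz <- cell$pause_s
    if (!is.na(pz) && pz > 0) {
      # suppression scale = magnitude of the least-negative net current over
      # the pause, so the simulated rate is zero through the drawn pause
      in_pause <- current$time > 0 & current$time <= pz
      i_max <- if (any(in_pause)) max(I[in_pause]) else
        stats::approx(current$time, I, xout = pz, rule = 2)$y
      i0 <- if (i_max < 0) -i_max else 1e-6
    } else i0 <- Inf
  }
  rate <- ifelse(I >= 0, pmin(rb + k * I^p, rate_cap),
                 rb * pmax(0, 1 + I / i0))
  structure(list(time = current$time, rate = rate, cell_id = cell$cell_id,
                 n_trials = NA_integer_, kind = "model"),
            class = "rate_trace")
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf("rate_trace (cell %s): %d samples, [%.2f, %.1f] s, peak %.1f Hz",
              x$cell_id, length(x$time), min(x$time), max(x$time),
              max(x$rate)))
  if (!is.na(x$n_trials)) cat(sprintf(", mean of %d trials", x$n_trials))
  cat("\n")
  invisible(x)
}

# numerical half-decay time of a trace: time from the (baseline-subtracted)
# peak to the first post-peak crossing of half the peak, linearly
# interpolated; NA when the trace never falls to half within the grid
half_decay_time <- function(time, value, baseline = 0) {
  v <- value - baseline
  ipk <- which.max(v)
  half <- v[ipk] / 2
  post <- seq(ipk, length(v))
  below <- post[v[post] <= half]
  if (!length(below)) return(NA_real_)
  j <- below[1]
  if (j == ipk) return(0)
  t_cross <- time[j - 1] + (time[j] - time[j - 1]) *
    (v[j - 1] - half) / (v[j - 1] - v[j])
  t_cross - time[ipk]
}
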