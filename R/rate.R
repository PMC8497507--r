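# Rate estimation: spike trains -> trial-averaged instantaneous firing rates.
#
# The instantaneous firing rate is the reciprocal-ISI step function (1/ISI on
# each inter-spike interval, zero outside the first..last spike), sampled on
# an analysis grid that is uniform before stimulus onset and log-spaced after
# offset so every decade carries equal weight in the subsequent fits. No
# kernel smoothing is applied; the log-Gaussian fit is the smoother.

#' Analysis time grid for rate estimation
#'
#' Uniform 10 ms samples over the pre-onset baseline window plus
#' \code{n_log} log-spaced samples from \code{t_log0} to \code{t_max} after
#' stimulus offset (t = 0 at offset).
#'
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param t_max last post-offset sample, s.
#' @param pre pre-onset span, s.
#' @param n_log number of log-spaced post-offset samples.
#' @param t_log0 first post-offset sample, s.
#' @return sorted numeric vector of times, s.
#' @export
analysis_grid <- function(protocol = stimulus_protocol(), t_max = 60,
                          pre = 5, n_log = 600, t_log0 = 0.005) {
  t_on <- -burst_duration(protocol)
  sort(unique(c(seq(t_on - pre, t_on, by = 0.01),
                exp(seq(log(t_log0), log(t_max), length.out = n_log)))))
}

#' Instantaneous firing rate of one spike train
#'
#' Step function equal to 1/ISI on each inter-spike interval and 0 outside
#' the span of the train, sampled on \code{grid}.
#'
#' @param spikes numeric vector of spike times (one trial), s.
#' @param grid sample times, s.
#' @param cell_id carried through to the output.
#' @return a \code{rate_trace}; if the train has fewer than two spikes the
#'   trace is all zero and flagged (\code{attr(, "degenerate")}).
#' @export
isi_rate <- function(spikes, grid, cell_id = NA) {
  stopifnot(!is.unsorted(grid, strictly = TRUE))
  spikes <- sort(spikes)
  rate <- numeric(length(grid))
  degenerate <- length(spikes) < 2
  if (!degenerate) {
    # interval index of each grid point; 0 or n = outside span
    idx <- findInterval(grid, spikes)
    inside <- idx >= 1 & idx < length(spikes) & grid >= spikes[1]
    isi <- diff(spikes)
    rate[inside] <- 1 / isi[idx[inside]]
  }
  structure(list(time = grid, rate = rate, cell_id = cell_id,
                 n_trials = 1L, kind = "isi"),
            class = "rate_trace", degenerate = degenerate)
}

#' Pointwise average of rate traces across trials
#'
#' @param traces list of \code{rate_trace}s on identical grids.
#' @return a \code{rate_trace} with \code{n_trials} recorded.
#' @export
average_trials <- function(traces) {
  stopifnot(length(traces) >= 1)
  g <- traces[[1]]$time
  for (tr in traces)
    if (length(tr$time) != length(g) || any(tr$time != g))
      stop("rate traces must share an identical time grid")
  m <- rowMeans(vapply(traces, `[[`, numeric(length(g)), "rate"))
  structure(list(time = g, rate = m, cell_id = traces[[1]]$cell_id,
                 n_trials = length(traces), kind = traces[[1]]$kind),
            class = "rate_trace")
}

#' Baseline firing statistics
#'
#' Mean and SD of the rate trace over a pre-onset window, plus the mean
#' inter-spike interval of pooled pre-onset spikes when trains are supplied.
#'
#' @param trace a (trial-averaged) \code{rate_trace}.
#' @param window \code{c(t0, t1)}, both before stimulus onset, length >= 2 s.
#' @param trains optional \code{spike_trains} for the ISI estimate.
#' @return list of class \code{baseline_stats}: \code{mean_hz}, \code{sd_hz},
#'   \code{mean_isi_s} (NA, flagged, for silent cells), \code{window}.
#' @export
estimate_baseline <- function(trace, window = NULL, trains = NULL) {
  if (is.null(window)) window <- c(min(trace$time), -0.25 + min(0, min(trace$time) + 5))
  if (window[1] < min(trace$time) || window[2] > max(trace$time))
    stop("baseline window outside the trace grid")
  if (diff(window) < 2) stop("baseline window must span at least 2 s")
  sel <- trace$time >= window[1] & trace$time <= window[2]
  m <- mean(trace$rate[sel]); s <- stats::sd(trace$rate[sel])
  isi <- NA_real_
  if (!is.null(trains)) {
    isis <- unlist(lapply(split_trials(trains), function(sp) {
      sp <- sp[sp >= window[1] & sp <= window[2]]
      if (length(sp) >= 2) diff(sp) else numeric(0)
    }))
    if (length(isis)) isi <- mean(isis)
  }
  structure(list(mean_hz = m, sd_hz = s, mean_isi_s = isi, window = window,
                 silent = m <= 0 || (is.na(isi) && !is.null(trains))),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("baseline: %.1f +/- %.1f Hz over [%.1f, %.2f] s",
              x$mean_hz, x$sd_hz, x$window[1], x$window[2]))
  if (!is.na(x$mean_isi_s)) cat(sprintf(", mean ISI %.0f ms", 1e3 * x$mean_isi_s))
  cat("\n")
  invisible(x)
}

#' Pause duration from spike trains
#'
#' Mean over trials of the first post-offset spike latency minus the
#' baseline mean ISI, floored at zero. Trials without a post-offset spike
#' contribute the recording end (censored; counted in the \code{censored}
#' attribute rather than dropped).
#'
#' @param trains a \code{spike_trains} data.frame.
#' @param baseline a \code{\link{estimate_baseline}} result with a defined
#'   mean ISI (spontaneously active cell); otherwise the pause is undefined
#'   (NA).
#' @param t_end recording end used for censored trials, s.
#' @return pause duration in seconds, with attribute \code{censored} (trial
#'   count); NA when the baseline ISI is undefined.
#' @export
pause_duration <- function(trains, baseline, t_end = max(trains$time, 0)) {
  if (is.na(baseline$mean_isi_s)) {
    out <- NA_real_; attr(out, "censored") <- 0L; return(out)
  }
  lat <- vapply(split_trials(trains), function(sp) {
    post <- sp[sp > 0]
    if (length(post)) post[1] else NA_real_
  }, numeric(1))
  censored <- sum(is.na(lat))
  lat[is.na(lat)] <- t_end
  out <- max(0, mean(lat) - baseline$mean_isi_s)
  attr(out, "censored") <- censored
  out
}
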