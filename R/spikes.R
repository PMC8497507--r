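#' Simulate spike trains from a rate trace
#'
#' Inhomogeneous Poisson process by thinning, with an absolute refractory
#' period. Thinning runs segment-wise on the trace grid: within each grid
#' interval, homogeneous candidates at the local rate envelope are accepted
#' with probability rate(t)/envelope (piecewise-linear interpolation of the
#' trace), then candidates closer than \code{refractory} to the previous
#' accepted spike are discarded. For rate << 1/refractory the expected count
#' over any window approximates the integral of the rate.
#'
#' @param rate a \code{rate_trace} (rate must be >= 0 everywhere).
#' @param n_trials number of trials.
#' @param refractory absolute refractory period, s.
#' @param seed optional integer seed (kept separate from population
#'   sampling: pass a different seed stream).
#' @return data.frame of class \code{spike_trains} with columns
#'   \code{cell_id}, \code{trial}, \code{time} (strictly increasing within a
#'   trial, offset-referenced, s). Attribute \code{n_trials} records trials
#'   with zero spikes as well.
#' @examples
#' rt <- structure(list(time = c(0, 10), rate = c(20, 20), cell_id = 1,
#'                      n_trials = NA, kind = "model"), class = "rate_trace")
#' sp <- generate_spikes(rt, n_trials = 3, seed = 1)
#' @export
generate_spikes <- function(rate, n_trials = 5, refractory = 0.002,
                            seed = NULL) {
  if (any(rate$rate < 0)) stop("rate trace contains negative values")
  stopifnot(n_trials >= 1, refractory >= 0)
  if (!is.null(seed)) set.seed(seed)
  tt <- rate$time; rr <- rate$rate
  nseg <- length(tt) - 1
  dt <- diff(tt)
  env <- pmax(rr[-length(rr)], rr[-1])      # local envelope per segment
  lam <- env * dt
  out <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    if (max(rr) <= 0) { out[[tr]] <- numeric(0); next }
    n_i <- stats::rpois(nseg, lam)
    tot <- sum(n_i)
    if (tot == 0) { out[[tr]] <- numeric(0); next }
    seg <- rep.int(seq_len(nseg), n_i)
    cand <- tt[seg] + stats::runif(tot) * dt[seg]
    r_at <- stats::approx(tt, rr, xout = cand, rule = 2)$y
    keep <- stats::runif(tot) < r_at / pmax(env[seg], 1e-12)
    sp <- sort(cand[keep])
    if (refractory > 0 && length(sp) > 1) {
      acc <- sp[1]; last <- sp[1]
      for (s in sp[-1]) if (s - last >= refractory) { acc <- c(acc, s); last <- s }
      sp <- acc
    }
    out[[tr]] <- sp
  }
  times <- unlist(out)
  df <- data.frame(
    cell_id = rep(rate$cell_id, length(times)),
    trial = rep(seq_len(n_trials), lengths(out)),
    time = times)
  attr(df, "n_trials") <- n_trials
  class(df) <- c("spike_trains", "data.frame")
  df
}

# split a spike_trains data.frame into per-trial time vectors
split_trials <- function(trains) {
  nt <- attr(trains, "n_trials")
  if (is.null(nt)) nt <- max(trains$trial)
  lapply(seq_len(nt), function(tr) sort(trains$time[trains$trial == tr]))
}
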