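# Biphasic metabotropic synaptic-current model.
#
# Total current (inward/excitatory positive) = mGluR1 - mGluR2/3 + ionotropic:
#   mGluR1   : slow log-Gaussian inward current, zero before stimulus offset;
#              its decay limb widens under DGK inhibition (dgk_scale).
#   mGluR2/3 : fast outward current rising from the first pulse of the
#              burst, decaying sharply after offset; terminates before the
#              mGluR1 peak.
#   ionotropic: small fast AMPA/NMDA transients at each pulse.

# outward (mGluR2/3) unit shape, normalized to 1 at stimulus offset:
# saturating exponential rise (tau_rise) from the first pulse at t1 while
# transmitter is present, then a Gaussian-in-time decay (accelerating, time
# scale tau_out) after offset as the G-protein cascade deactivates. The
# accelerating decay lets the outward current dominate the net current
# through the firing pause yet terminate before the inward mGluR1 peak.
.outward_shape <- function(t, t1, tau_out, tau_rise) {
  out <- numeric(length(t))
  on <- t >= t1
  rise <- 1 - exp(-(t[on] - t1) / tau_rise)
  decay <- exp(-(pmax(0, t[on]) / tau_out)^2)
  out[on] <- rise * decay / (1 - exp(t1 / tau_rise))
  out
}

# log-Gaussian inward shape with optional decay-limb widening (peak unchanged)
.inward_shape <- function(t, mu, sigma, dgk_scale = 1) {
  out <- numeric(length(t))
  on <- t > 0
  lt <- log(t[on])
  w <- ifelse(lt > mu, sigma * dgk_scale, sigma)
  out[on] <- exp(-((lt - mu) / w)^2)
  out
}

# analytic charge of the log-Gaussian inward component (one burst,
# dgk_scale = 1): integral of A exp(-((ln t - mu)/sigma)^2) dt over (0, Inf)
.log_gaussian_charge <- function(A, mu, sigma) {
  A * exp(mu) * sigma * sqrt(pi) * exp(sigma^2 / 4)
}

#' Derive current-side parameters from rate-side parameters
#'
#' Inverts the supra-linear f-I transform so that the synthesized current,
#' passed through \code{rate = baseline + k I^p}, reproduces each cell's
#' target log-Gaussian rate exactly: \code{sigma_I = sigma_r sqrt(p)},
#' \code{mu_I = mu_r}, \code{A_I = (A_r/k)^(1/p)}. The outward (mGluR2/3)
#' amplitude is the larger of the empirical pause-amplitude relation
#' (log10 pause = -0.42 + 0.01 A_out, inverted) and the minimum amplitude
#' that keeps the net current outward throughout the drawn pause (times a
#' 1.2 safety factor); its decay time scale (pause/1.4) makes the outward
#' component fall below 5\% of its peak before the inward component peaks.
#' The fast
#' ionotropic amplitude is calibrated so that component carries
#' \code{fast_charge_frac} of the total excitatory charge.
#'
#' @param cell one or more rows of a \code{ubc_population} data.frame (needs
#'   \code{class}, \code{amp_hz}, \code{mu_r}, \code{sigma_r},
#'   \code{pause_s}).
#' @param p f-I exponent (> 1).
#' @param k f-I gain, Hz/pA^p.
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param params optional \code{\link{continuum_params}} supplying
#'   \code{fast_charge_frac}, \code{tau_rise_s}, \code{tau_fast_s}.
#' @return the input data.frame with current-side columns filled
#'   (\code{sigma_i}, \code{mu_i}, \code{amp_in_pa}, \code{amp_out_pa},
#'   \code{tau_out_s}, \code{amp_fast_pa}).
#' @export
derive_current_params <- function(cell, p, k, protocol = stimulus_protocol(),
                                  params = NULL) {
  if (any(cell$amp_hz < 0, na.rm = TRUE)) stop("amp_hz must be >= 0")
  if (k <= 0) stop("f-I gain k must be positive")
  frac <- if (!is.null(params)) params$fast_charge_frac else 0.09
  tau_rise <- if (!is.null(params)) params$tau_rise_s else 0.05
  tau_fast <- if (!is.null(params)) params$tau_fast_s else 0.005
  bd <- burst_duration(protocol)

  cell$sigma_i <- cell$sigma_r * sqrt(p)
  cell$mu_i <- cell$mu_r
  cell$amp_in_pa <- ifelse(cell$amp_hz > 0, (cell$amp_hz / k)^(1 / p), 0)

  n <- nrow(cell)
  amp_out <- numeric(n); tau_out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pz <- cell$pause_s[i]
    if (is.na(pz) || pz <= 0) next
    pause_rel <- (log10(pz) + 0.42) / 0.01
    tau_out[i] <- pz / 1.4
    if (cell$class[i] == "off") {
      amp_out[i] <- max(pause_rel, 20)
    } else {
      g_p <- .outward_shape(pz, -bd, tau_out[i], tau_rise)
      m1_p <- cell$amp_in_pa[i] *
        .inward_shape(pz, cell$mu_i[i], cell$sigma_i[i])
      amp_out[i] <- max(pause_rel, 1.2 * m1_p / g_p, 1)
    }
  }
  cell$amp_out_pa <- amp_out
  cell$tau_out_s <- tau_out

  q_m1 <- ifelse(cell$amp_in_pa > 0,
                 .log_gaussian_charge(cell$amp_in_pa, cell$mu_i, cell$sigma_i),
                 0)
  amp_fast <- frac / (1 - frac) * q_m1 / (protocol$n_pulses * tau_fast)
  # In pausing excitatory cells the fast transient of the last pulse spills
  # past offset; cap its amplitude so the outward current dominates it and
  # the net current stays most negative at the pause end (otherwise the
  # pause would be cut short by transient spikes at ~5-15 ms).
  for (i in seq_len(n)) {
    pz <- cell$pause_s[i]
    if (is.na(pz) || pz <= 0 || cell$class[i] != "biphasic") next
    tg <- seq(1e-3, min(pz, 10 * tau_fast), length.out = 40)
    m23 <- function(t) cell$amp_out_pa[i] *
      .outward_shape(t, -bd, cell$tau_out_s[i], tau_rise)
    m1 <- function(t) cell$amp_in_pa[i] *
      .inward_shape(t, cell$mu_i[i], cell$sigma_i[i])
    margin <- (m23(tg) - m1(tg)) - (m23(pz) - m1(pz))
    # summed-pulse envelope of the fast transient, relative to unit amplitude
    iono_unit <- vapply(tg, function(t)
      sum(exp(-(t - pulse_times(protocol)) / tau_fast)[t >= pulse_times(protocol)]),
      numeric(1))
    cap <- 0.8 * min(pmax(margin, 0) / pmax(iono_unit, 1e-12))
    amp_fast[i] <- min(amp_fast[i], max(cap, 0))
  }
  cell$amp_fast_pa <- amp_fast
  if (is.null(cell$dgk_scale)) cell$dgk_scale <- 1
  cell
}

#' Time grid for current and rate traces
#'
#' Union of a uniform 10 ms pre-onset baseline segment, a fine 0.5 ms
#' segment through the stimulus burst (resolving the fast ionotropic
#' transients), and \code{n_log} log-spaced points from \code{t_log0} to
#' \code{t_max} after offset. t = 0 at stimulus offset.
#'
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param t_max end of the grid, s.
#' @param pre pre-onset baseline span, s.
#' @param n_log number of log-spaced post-offset points.
#' @param t_log0 first post-offset log point, s.
#' @return sorted numeric vector of times, s.
#' @export
make_time_grid <- function(protocol = stimulus_protocol(), t_max = 120,
                           pre = 5.2, n_log = 600, t_log0 = 0.005) {
  t_on <- -burst_duration(protocol)
  g <- c(seq(t_on - pre, t_on, by = 0.01),
         seq(t_on, 0.02, by = 5e-4),
         exp(seq(log(t_log0), log(t_max), length.out = n_log)))
  if (protocol$n_bursts > 1) {
    starts <- (seq_len(protocol$n_bursts) - 1) * protocol$burst_interval
    per <- c(seq(t_on, 0.02, by = 5e-4),
             exp(seq(log(t_log0), log(max(t_max - max(starts),
                                          protocol$burst_interval)),
                     length.out = n_log)))
    g <- c(g, as.vector(outer(per, starts[-1], `+`)))
    g <- g[g <= t_max + max(starts)]
  }
  sort(unique(g))
}

#' Synthesize a cell's synaptic current trace
#'
#' Builds the three-component current on the given grid. For multi-burst
#' protocols, components from successive bursts sum linearly (no short-term
#' plasticity). Metabotropic amplitudes scale linearly with the pulse count
#' relative to the 20-pulse reference protocol.
#'
#' @param cell a single row of a \code{ubc_population}.
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param grid time grid from \code{\link{make_time_grid}}; must extend to at
#'   least 5 current half-decay times after offset.
#' @param params optional \code{\link{continuum_params}} (time constants).
#' @param ref_pulses reference pulse count for amplitude scaling.
#' @return an object of class \code{current_trace}: list with \code{time},
#'   \code{total}, and component vectors \code{mGluR1}, \code{mGluR23},
#'   \code{ionotropic} (each non-negative; total = mGluR1 - mGluR23 +
#'   ionotropic), in pA, inward positive.
#' @export
synth_current <- function(cell, protocol = stimulus_protocol(),
                          grid = make_time_grid(protocol),
                          params = NULL, ref_pulses = 20) {
  stopifnot(nrow(cell) == 1)
  tau_rise <- if (!is.null(params)) params$tau_rise_s else 0.05
  tau_fast <- if (!is.null(params)) params$tau_fast_s else 0.005
  bd <- burst_duration(protocol)
  if (cell$amp_in_pa > 0) {
    hd <- exp(cell$mu_i) * (exp(cell$sigma_i * cell$dgk_scale * SQRT_LN2) - 1)
    if (max(grid) < 5 * hd)
      stop(sprintf("grid too short: needs to span at least %.1f s post-offset",
                   5 * hd))
  }
  scale <- protocol$n_pulses / ref_pulses
  starts <- if (protocol$n_bursts > 1)
    (seq_len(protocol$n_bursts) - 1) * protocol$burst_interval else 0

  m1 <- m23 <- iono <- numeric(length(grid))
  for (s0 in starts) {
    if (cell$amp_in_pa > 0)
      m1 <- m1 + scale * cell$amp_in_pa *
        .inward_shape(grid - s0, cell$mu_i, cell$sigma_i, cell$dgk_scale)
    if (cell$amp_out_pa > 0)
      m23 <- m23 + scale * cell$amp_out_pa *
        .outward_shape(grid - s0, -bd, cell$tau_out_s, tau_rise)
  }
  if (cell$amp_fast_pa > 0) {
    for (tp in pulse_times(protocol)) {
      on <- grid >= tp
      iono[on] <- iono[on] + cell$amp_fast_pa * exp(-(grid[on] - tp) / tau_fast)
    }
  }
  structure(list(time = grid, total = m1 - m23 + iono,
                 mGluR1 = m1, mGluR23 = m23, ionotropic = iono,
                 cell_id = cell$cell_id, protocol = protocol),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(paste0("current_trace (cell %s): %d samples, ",
                     "[%.2f, %.1f] s, peak %+.1f / trough %+.1f pA\n"),
              x$cell_id, length(x$time), min(x$time), max(x$time),
              max(x$total), min(x$total)))
  invisible(x)
}

#' Signed and component charges of a current trace
#'
#' Trapezoidal integrals of the total and per-component currents over the
#' trace. The excitatory charge is mGluR1 + ionotropic.
#'
#' @param trace a \code{current_trace}.
#' @return named vector (pA s): \code{total}, \code{mGluR1}, \code{mGluR23},
#'   \code{ionotropic}, \code{excitatory}.
#' @export
charge <- function(trace) {
  q <- function(y) sum(diff(trace$time) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  c(total = q(trace$total), mGluR1 = q(trace$mGluR1),
    mGluR23 = q(trace$mGluR23), ionotropic = q(trace$ionotropic),
    excitatory = q(trace$mGluR1) + q(trace$ionotropic))
}

#' Pharmacology emulation
#'
#' Returns a modified copy of the cell parameters under a receptor blockade
#' or DGK inhibition; the input is not mutated.
#' \describe{
#'   \item{mGluR1_block}{removes the slow inward component (A_I = 0).}
#'   \item{mGluR23_block}{removes the outward component (A_out = 0), and with
#'     it the firing pause.}
#'   \item{ampa_nmda_block}{removes the fast ionotropic transients.}
#'   \item{dgk_inhibitor}{multiplies \code{dgk_scale} by \code{lambda},
#'     widening the inward component's decay limb only; its peak value is
#'     unchanged.}
#' }
#'
#' @param cell one or more rows of a \code{ubc_population}.
#' @param condition one of \code{"mGluR1_block"}, \code{"mGluR23_block"},
#'   \code{"ampa_nmda_block"}, \code{"dgk_inhibitor"}.
#' @param lambda DGK width factor (default 2).
#' @return modified copy of \code{cell}.
#' @export
apply_pharmacology <- function(cell, condition, lambda = 2) {
  valid <- c("mGluR1_block", "mGluR23_block", "ampa_nmda_block",
             "dgk_inhibitor")
  if (!is.character(condition) || length(condition) != 1 ||
      !condition %in% valid)
    stop("unknown condition; valid conditions: ",
         paste(valid, collapse = ", "))
  out <- cell
  switch(condition,
    mGluR1_block = { out$amp_in_pa <- 0 },
    mGluR23_block = { out$amp_out_pa <- 0 },
    ampa_nmda_block = { out$amp_fast_pa <- 0 },
    dgk_inhibitor = { out$dgk_scale <- out$dgk_scale * lambda })
  out
}
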