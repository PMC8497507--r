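# Population-level statistics: sorted heatmaps, rank regressions, the
# inverted soft-plus amplitude law, log-uniformity tests, and the
# 1/sqrt(N)-normalized population-amplitude decay with its shifted
# power-law fit.

#' Sorted, normalized population response matrix
#'
#' Excited and biphasic cells are sorted ascending by half-decay time and
#' normalized by their peak rate; suppressed cells are appended sorted by
#' pause duration and normalized by their baseline rate (rows sit near 1 at
#' baseline and near 0 during the pause). Unresponsive cells are excluded
#' (their ids are reported). Ties in half-decay are broken by peak time,
#' then cell id, so row order is reproducible.
#'
#' @param features the \code{features} data.frame of a
#'   \code{\link{simulate_ubc_experiment}} result (needs \code{class},
#'   \code{half_decay_s}, \code{pause_s}, \code{peak_time_s},
#'   \code{baseline_hz}).
#' @param traces list of trial-averaged \code{rate_trace}s, one per row of
#'   \code{features}, on a common grid.
#' @param t_linear_max extent of the linear-time matrix, s.
#' @param dt_linear sample step of the linear-time matrix, s.
#' @return list of class \code{population_matrix}: \code{linear} and
#'   \code{log10} (each \code{time} + cells x time \code{matrix}),
#'   \code{order} (cell ids, row order), \code{normalization} per row,
#'   \code{excluded}.
#' @export
sort_and_normalize <- function(features, traces, t_linear_max = 10,
                               dt_linear = 0.01) {
  stopifnot(nrow(features) == length(traces))
  exc <- which(features$class %in% c("excited", "biphasic"))
  sup <- which(features$class == "suppressed")
  drop <- which(features$class == "unresponsive")
  if (length(drop))
    message(length(drop), " unresponsive cell(s) excluded: ",
            paste(features$cell_id[drop], collapse = ", "))
  exc <- exc[order(features$half_decay_s[exc], features$peak_time_s[exc],
                   features$cell_id[exc])]
  sup <- sup[order(features$pause_s[sup], features$cell_id[sup])]
  rows <- c(exc, sup)
  norm_mode <- c(rep("peak", length(exc)), rep("baseline", length(sup)))

  grid <- traces[[1]]$time
  post <- grid > 0
  t_log <- grid[post]
  t_lin <- seq(0, t_linear_max, by = dt_linear)
  m_log <- matrix(NA_real_, length(rows), length(t_log))
  m_lin <- matrix(NA_real_, length(rows), length(t_lin))
  for (j in seq_along(rows)) {
    i <- rows[j]
    r <- traces[[i]]$rate
    denom <- if (norm_mode[j] == "peak") max(r[post]) else
      max(features$baseline_hz[i], 1e-9)
    m_log[j, ] <- r[post] / denom
    m_lin[j, ] <- stats::approx(grid, r, xout = t_lin, rule = 2)$y / denom
  }
  structure(list(linear = list(time = t_lin, matrix = m_lin),
                 log10 = list(time = t_log, matrix = m_log),
                 order = features$cell_id[rows], normalization = norm_mode,
                 excluded = features$cell_id[drop]),
            class = "population_matrix")
}

# OLS helper returning the package's standard regression summary
.rank_ols <- function(y, x, transform) {
  ok <- is.finite(y) & is.finite(x)
  if (sum(ok) < 4)
    return(list(slope = NA_real_, intercept = NA_real_, r2_adj = NA_real_,
                n = sum(ok), transform = transform, n_excluded = sum(!ok)))
  m <- stats::lm(y[ok] ~ x[ok])
  r2 <- 1 - sum(stats::resid(m)^2) / sum((y[ok] - mean(y[ok]))^2)
  list(slope = unname(stats::coef(m)[2]), intercept = unname(stats::coef(m)[1]),
       r2_adj = adjusted_r2(r2, sum(ok), 1), n = sum(ok),
       transform = transform, n_excluded = sum(!ok))
}

#' Rank regressions of the sorted continuum
#'
#' OLS of log10 peak time, log10 half-width and log10 pause against cell
#' rank (sorted ascending by half-decay for excited/biphasic cells), plus
#' raw half-width/peak-time ratio and log-Gaussian width sigma against rank.
#' Cells with censored or undetected pauses are excluded from the pause
#' regression (count reported).
#'
#' @param features features data.frame (see
#'   \code{\link{sort_and_normalize}}); only excited/biphasic rows enter the
#'   peak-time, half-width, ratio and sigma regressions.
#' @param min_pause pauses below this value are treated as undetected, s.
#' @return named list of regression summaries (\code{slope},
#'   \code{intercept}, \code{r2_adj}, \code{n}, \code{transform}):
#'   \code{peak_time}, \code{half_width}, \code{pause}, \code{hw_pt_ratio},
#'   \code{sigma}.
#' @export
rank_regressions <- function(features, min_pause = 1e-3) {
  exc <- features[features$class %in% c("excited", "biphasic"), ]
  exc <- exc[order(exc$half_decay_s, exc$peak_time_s, exc$cell_id), ]
  if (nrow(exc) < 10) stop("need at least 10 excitatory cells")
  rank <- seq_len(nrow(exc))
  out <- list(
    peak_time = .rank_ols(log10(exc$peak_time_s), rank, "log10-response"),
    half_width = .rank_ols(log10(exc$half_width_s), rank, "log10-response"),
    hw_pt_ratio = .rank_ols(exc$hw_pt_ratio, rank, "raw"),
    sigma = .rank_ols(exc$sigma, rank, "raw"))

  # pause regression over the full sorted population (suppressed appended)
  sup <- features[features$class == "suppressed", ]
  sup <- sup[order(sup$pause_s, sup$cell_id), ]
  all_sorted <- rbind(exc, sup)
  pz <- all_sorted$pause_s
  pz[!is.finite(pz) | pz < min_pause] <- NA
  out$pause <- .rank_ols(log10(pz), seq_len(nrow(all_sorted)),
                         "log10-response")
  out
}

#' Inverted soft-plus fit of the amplitude-vs-rank decline
#'
#' Fits \code{a - ln(1 + e^(x/b))} to log10 amplitudes against cell rank by
#' nonlinear least squares: a plateau at \code{a} for low ranks giving way
#' to a log-linear decrease of slope \code{-1/b}.
#'
#' @param log10_amp log10 amplitudes (Hz), ordered by rank.
#' @param rank cell ranks (default 1..n).
#' @return object of class \code{softplus_fit}: \code{a}, \code{b},
#'   \code{residuals}, \code{converged}, \code{degenerate} (near-constant
#'   input drives b very large).
#' @export
fit_softplus_amplitude <- function(log10_amp, rank = seq_along(log10_amp)) {
  ok <- is.finite(log10_amp)
  if (sum(ok) < 10) stop("need at least 10 excitatory cells")
  y <- log10_amp[ok]; x <- rank[ok]
  m <- tryCatch(
    minpack.lm::nlsLM(y ~ a - log(1 + exp(x / b)),
                      start = list(a = max(y) + 0.7, b = length(x) / 4),
                      lower = c(-Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(m)) {
    fit <- list(a = NA_real_, b = NA_real_, residuals = NULL,
                converged = FALSE, degenerate = FALSE)
  } else {
    cf <- stats::coef(m)
    fit <- list(a = unname(cf["a"]), b = unname(cf["b"]),
                residuals = stats::resid(m), converged = TRUE,
                degenerate = unname(cf["b"]) > 50 * length(x))
  }
  fit$rank <- x; fit$log10_amp <- y
  class(fit) <- "softplus_fit"
  fit
}

#' @export
print.softplus_fit <- function(x, ...) {
  if (!x$converged) cat("soft-plus amplitude fit: did not converge\n")
  else cat(sprintf(paste0("soft-plus amplitude fit: a = %.3f (log10 Hz), ",
                          "b = %.2f (tail slope %.4f/rank)%s\n"),
                   x$a, x$b, -1 / x$b,
                   if (x$degenerate) " [degenerate: near-constant input]"
                   else ""))
  invisible(x)
}

#' @export
predict.softplus_fit <- function(object, rank = object$rank, ...) {
  object$a - log(1 + exp(rank / object$b))
}

#' One-sample Kolmogorov-Smirnov test for log-uniformity
#'
#' Tests whether log10-transformed values follow Uniform(lo, hi). For
#' synthetic data the range should be the configured generator bounds
#' (testing against the intended distribution); for external data the
#' empirical min/max may be used (flagged, slightly conservative).
#'
#' @param log10_values log10-transformed values.
#' @param range \code{c(lo, hi)}; all values must lie inside.
#' @param range_source \code{"configured"} or \code{"data"}.
#' @return list: \code{statistic}, \code{p_value}, \code{n}, \code{range},
#'   \code{range_source}.
#' @export
ks_uniformity <- function(log10_values, range,
                          range_source = c("configured", "data")) {
  range_source <- match.arg(range_source)
  if (any(log10_values < range[1] - 1e-9 | log10_values > range[2] + 1e-9))
    stop("values outside the stated range")
  kt <- suppressWarnings(
    stats::ks.test(log10_values, "punif", range[1], range[2]))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = length(log10_values), range = range, range_source = range_source)
}

#' Population response amplitude
#'
#' L2 norm of the population activity vector (each dimension one cell's
#' instantaneous firing rate), normalized by 1/sqrt(N) to control for the
#' expected sqrt(N) growth: at each time,
#' \code{sqrt(sum_i rate_i^2) / sqrt(N)} = the RMS rate across cells.
#'
#' @param traces list of \code{rate_trace}s on a common grid, or a cells x
#'   time rate matrix.
#' @param time required when \code{traces} is a matrix.
#' @param n_stim stimulus count tag carried to the power-law fit.
#' @return list of class \code{population_amplitude}: \code{time},
#'   \code{amplitude}, \code{n_cells}, \code{n_stim}.
#' @export
population_amplitude <- function(traces, time = NULL, n_stim = NA) {
  if (is.matrix(traces)) {
    stopifnot(!is.null(time), ncol(traces) == length(time))
    m <- traces
  } else {
    time <- traces[[1]]$time
    for (tr in traces)
      if (length(tr$time) != length(time) || any(tr$time != time))
        stop("rate traces must share an identical time grid")
    m <- do.call(rbind, lapply(traces, `[[`, "rate"))
  }
  structure(list(time = time, amplitude = sqrt(colMeans(m^2)),
                 n_cells = nrow(m), n_stim = n_stim),
            class = "population_amplitude")
}

# sum of squared log-residuals of the shifted power law over all stimulus
# counts; amps = list of population_amplitude restricted to the tail domain
.powerlaw_obj <- function(par, amps) {
  C <- exp(par[1]); t_min <- exp(par[2]); beta <- par[3]; alpha <- par[4]
  s <- 0
  for (a in amps) {
    pred <- log(C) + log(a$n_stim) + alpha * log(a$time + t_min * a$n_stim^beta)
    s <- s + sum((log(a$amplitude) - pred)^2)
  }
  s
}

#' Shifted power-law fit of the population-amplitude decay
#'
#' Joint nonlinear least squares, in log-log space over the post-offset tail
#' domain, of \deqn{A_n(t) = C n (t + t_{min} n^\beta)^\alpha} across all
#' supplied stimulus counts n, with shared parameters. \code{alpha} is the
#' critical exponent of the decay. An optional bootstrap over cells
#' (resampling rows of the per-cell rate matrices and refitting) yields a
#' 95\% CI for \code{alpha}.
#'
#' @param amps list of \code{\link{population_amplitude}} objects, one per
#'   stimulus count (each with \code{n_stim} set).
#' @param t_range tail domain for fitting, s.
#' @param cell_matrices optional list (same order) of cells x time rate
#'   matrices for the bootstrap.
#' @param n_boot bootstrap resamples (0 = no CI).
#' @param seed bootstrap seed.
#' @return object of class \code{powerlaw_fit}: \code{C}, \code{t_min},
#'   \code{beta}, \code{alpha}, \code{alpha_ci95}, \code{converged},
#'   \code{non_decaying} (alpha >= 0).
#' @export
fit_shifted_powerlaw <- function(amps, t_range = c(0.1, 30),
                                 cell_matrices = NULL, n_boot = 0,
                                 seed = 1) {
  if (length(amps) < 1) stop("need at least one amplitude curve")
  if (any(vapply(amps, function(a) is.na(a$n_stim), logical(1))))
    stop("every amplitude curve needs n_stim")
  clip <- function(a) {
    sel <- a$time >= t_range[1] & a$time <= t_range[2] & a$amplitude > 0
    list(time = a$time[sel], amplitude = a$amplitude[sel], n_stim = a$n_stim)
  }
  tails <- lapply(amps, clip)

  fit_once <- function(tl) {
    # initialize alpha from the overall log-log slope of the first curve
    lt <- log(tl[[1]]$time); ly <- log(tl[[1]]$amplitude)
    a0 <- min(-0.1, unname(stats::coef(stats::lm(ly ~ lt))[2]))
    p0 <- c(log(max(tl[[1]]$amplitude) / tl[[1]]$n_stim), log(0.2), 0.5, a0)
    op <- stats::optim(p0, .powerlaw_obj, amps = tl, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    op2 <- stats::optim(op$par, .powerlaw_obj, amps = tl, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-12))
    if (op2$value <= op$value) op <- op2
    c(C = exp(op$par[1]), t_min = exp(op$par[2]), beta = op$par[3],
      alpha = op$par[4], value = op$value,
      converged = as.numeric(op$convergence == 0))
  }
  est <- fit_once(tails)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && !is.null(cell_matrices)) {
    set.seed(seed)
    n_cells <- nrow(cell_matrices[[1]])
    boot_alpha <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_cells, replace = TRUE)
      tl <- lapply(seq_along(amps), function(j) {
        a <- population_amplitude(cell_matrices[[j]][idx, , drop = FALSE],
                                  time = amps[[j]]$time,
                                  n_stim = amps[[j]]$n_stim)
        clip(a)
      })
      fit_once(tl)["alpha"]
    }, numeric(1))
    ci <- unname(stats::quantile(boot_alpha, c(0.025, 0.975)))
  }
  structure(list(C = unname(est["C"]), t_min = unname(est["t_min"]),
                 beta = unname(est["beta"]), alpha = unname(est["alpha"]),
                 alpha_ci95 = ci, converged = est["converged"] == 1,
                 non_decaying = est["alpha"] >= 0, t_range = t_range,
                 n_curves = length(amps)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(paste0("shifted power-law fit over %d curve(s): alpha = %.3f",
                     " (C = %.3g, t_min = %.3g s, beta = %.3f)"),
              x$n_curves, x$alpha, x$C, x$t_min, x$beta))
  if (all(is.finite(x$alpha_ci95)))
    cat(sprintf(", 95%% CI (%.3f, %.3f)", x$alpha_ci95[1], x$alpha_ci95[2]))
  if (x$non_decaying) cat("  [non-decaying: alpha >= 0]")
  cat("\n")
  invisible(x)
}

#' @export
predict.powerlaw_fit <- function(object, time, n_stim, ...) {
  object$C * n_stim * (time + object$t_min * n_stim^object$beta)^object$alpha
}
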