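# End-to-end drivers: population -> currents -> rates -> spikes -> features.

#' Analyze one cell's spike trains
#'
#' Runs the measurement pipeline on a set of trials: per-trial reciprocal-ISI
#' rates, trial average, baseline statistics, latency-based pause, a
#' log-Gaussian fit (censoring the suppressed window when a pause is
#' detected), closed-form features and the response classification.
#'
#' @param trains a \code{spike_trains} data.frame for one cell.
#' @param grid analysis grid (see \code{\link{analysis_grid}}).
#' @param protocol the \code{\link{stimulus_protocol}} used.
#' @param pause_isi_mult pause-detection threshold in baseline ISIs (also
#'   passed to \code{\link{classify_response}}).
#' @param mask_factor censor the fit below \code{mask_factor} times the
#'   measured pause for pausing cells.
#' @param t_fit_min earliest time entering the log-Gaussian fit, s. The
#'   first ~20 ms after offset are dominated by the fast ionotropic
#'   transient and by inter-spike intervals bridging the stimulus burst;
#'   feature extraction targets the metabotropic response.
#' @return list: \code{rate} (trial-averaged \code{rate_trace}),
#'   \code{baseline}, \code{pause}, \code{fit}, \code{features},
#'   \code{class}.
#' @export
analyze_cell <- function(trains, grid, protocol = stimulus_protocol(),
                         pause_isi_mult = 3, mask_factor = 1.75,
                         t_fit_min = 0.02) {
  trials <- split_trials(trains)
  cell_id <- if (nrow(trains)) trains$cell_id[1] else NA
  traces <- lapply(trials, isi_rate, grid = grid, cell_id = cell_id)
  avg <- average_trials(traces)
  t_on <- -burst_duration(protocol)
  bl <- estimate_baseline(avg, window = c(min(grid), t_on - 0.25),
                          trains = trains)
  pz <- pause_duration(trains, bl, t_end = max(grid))
  pause_detected <- !is.na(pz) && !is.na(bl$mean_isi_s) &&
    pz >= pause_isi_mult * bl$mean_isi_s
  mask <- if (pause_detected) max(mask_factor * pz, t_fit_min) else t_fit_min
  # for pausing cells the excitation peak follows the pause, and with the
  # suppressed window censored an extrapolated below-window peak is a
  # degenerate solution: constrain mu inside the fit window
  mu_lo <- if (pause_detected) log(mask) else log(0.005)
  fit <- fit_log_gaussian(avg, bl, mask_below = mask,
                          bounds_mu = c(mu_lo, log(60)), trains = trains)
  feats <- features_from_fit(fit, pz)
  cls <- classify_response(feats, bl, pause_isi_mult = pause_isi_mult)
  list(rate = avg, baseline = bl, pause = pz, fit = fit,
       features = feats, class = cls)
}

#' Simulate and analyze a full UBC population
#'
#' The complete round trip: sample per-cell parameters from the continuum,
#' synthesize synaptic currents, apply the supra-linear f-I transform,
#' draw stochastic spike trains, and run the measurement pipeline on every
#' cell. The spike-generation RNG stream is separated from the
#' population-sampling stream.
#'
#' @param params a \code{\link{continuum_params}}.
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param n_trials trials per cell.
#' @param seed integer seed controlling both streams.
#' @param t_max_model extent of the model (current/rate) grid, s.
#' @param keep_traces also return model current and rate traces per cell.
#' @param pharmacology optional condition applied to every cell before
#'   current synthesis (see \code{\link{apply_pharmacology}}).
#' @param pool_widths shrink per-cell log-Gaussian widths toward the
#'   population mean by random-effects pooling
#'   (\code{\link{pool_log_widths}}); width-derived features (half-width,
#'   half-decay, ratio) are recomputed from the pooled widths.
#' @return list of class \code{ubc_experiment}: \code{population} (the
#'   generated parameters), \code{features} (one row per cell: measured
#'   features + classification), \code{trains}, and optionally
#'   \code{currents}/\code{rates}.
#' @examples
#' \donttest{
#' ex <- simulate_ubc_experiment(seed = 1)
#' table(ex$features$class)
#' }
#' @export
simulate_ubc_experiment <- function(params = continuum_params(),
                                    protocol = stimulus_protocol(),
                                    n_trials = 5, seed = 1,
                                    t_max_model = 120,
                                    keep_traces = FALSE,
                                    pharmacology = NULL,
                                    pool_widths = TRUE) {
  pop <- sample_population(params, protocol, seed = seed)
  if (!is.null(pharmacology)) pop <- apply_pharmacology(pop, pharmacology)
  grid_model <- make_time_grid(protocol, t_max = t_max_model)
  grid_meas <- analysis_grid(protocol)

  res <- vector("list", nrow(pop))
  trains_all <- vector("list", nrow(pop))
  currents <- rates <- if (keep_traces) vector("list", nrow(pop)) else NULL
  for (i in seq_len(nrow(pop))) {
    cell <- pop[i, ]
    cur <- synth_current(cell, protocol, grid_model, params)
    rt <- f_i_transform(cur, cell, params$fi_exponent, params$fi_gain)
    trains <- generate_spikes(rt, n_trials = n_trials,
                              seed = seed * 1000L + cell$cell_id)
    res[[i]] <- analyze_cell(trains, grid_meas, protocol)
    trains_all[[i]] <- trains
    if (keep_traces) { currents[[i]] <- cur; rates[[i]] <- rt }
  }

  features <- data.frame(
    cell_id = pop$cell_id,
    true_class = pop$class,
    class = vapply(res, `[[`, character(1), "class"),
    baseline_hz = vapply(res, function(r) r$baseline$mean_hz, numeric(1)),
    amplitude_hz = vapply(res, function(r) r$features$amplitude, numeric(1)),
    peak_time_s = vapply(res, function(r) r$features$peak_time, numeric(1)),
    half_width_s = vapply(res, function(r) r$features$half_width, numeric(1)),
    half_decay_s = vapply(res, function(r) r$features$half_decay, numeric(1)),
    hw_pt_ratio = vapply(res, function(r) r$features$hw_pt_ratio, numeric(1)),
    pause_s = vapply(res, function(r) as.numeric(r$pause), numeric(1)),
    sigma = vapply(res, function(r) if (is.null(r$fit$sigma)) NA_real_
                                    else r$fit$sigma, numeric(1)),
    r2_adj = vapply(res, function(r) if (is.null(r$fit$r2_adj)) NA_real_
                                     else r$fit$r2_adj, numeric(1)),
    low_confidence = vapply(res, function(r)
      isTRUE(r$features$low_confidence), logical(1)),
    se_sigma = vapply(res, function(r) if (is.null(r$fit$se_sigma)) NA_real_
                                       else r$fit$se_sigma, numeric(1)),
    stringsAsFactors = FALSE)

  pool <- NULL
  if (pool_widths) {
    sel <- features$class %in% c("excited", "biphasic") &
      !features$low_confidence & is.finite(features$sigma)
    if (sum(sel) >= 3) {
      pool <- pool_log_widths(features$sigma[sel], features$se_sigma[sel])
      features$sigma[sel] <- pool$shrunk
      s <- features$sigma[sel] * SQRT_LN2
      pk <- features$peak_time_s[sel]
      features$half_width_s[sel] <- 2 * pk * sinh(s)
      features$half_decay_s[sel] <- pk * (exp(s) - 1)
      features$hw_pt_ratio[sel] <- 2 * sinh(s)
    }
  }

  out <- list(population = pop, features = features, trains = trains_all,
              analyses = res, protocol = protocol, params = params,
              width_pool = pool,
              currents = currents, rates = rates, seed = seed)
  class(out) <- "ubc_experiment"
  out
}

#' @export
print.ubc_experiment <- function(x, ...) {
  cat(sprintf("UBC experiment: %d cells, %s trials (seed %s)\n",
              nrow(x$population),
              length(split_trials(x$trains[[1]])), x$seed))
  print(table(measured = x$features$class))
  invisible(x)
}

#' Write the population-analysis outputs of an experiment
#'
#' Writes \code{features.csv} (one row per cell), \code{regressions.csv},
#' the sorted heatmap matrices (linear and log10 time axes) as CSV, and the
#' population amplitude as CSV into a directory.
#'
#' @param ex a \code{\link{simulate_ubc_experiment}} result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_population_results <- function(ex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ex$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  rr <- rank_regressions(ex$features)
  utils::write.csv(
    data.frame(quantity = names(rr),
               slope = vapply(rr, `[[`, numeric(1), "slope"),
               intercept = vapply(rr, `[[`, numeric(1), "intercept"),
               r2_adj = vapply(rr, `[[`, numeric(1), "r2_adj"),
               n = vapply(rr, `[[`, numeric(1), "n")),
    file.path(dir, "regressions.csv"), row.names = FALSE)
  traces <- lapply(ex$analyses, `[[`, "rate")
  pm <- sort_and_normalize(ex$features, traces)
  for (ax in c("linear", "log10")) {
    m <- rbind(pm[[ax]]$time, pm[[ax]]$matrix)
    rownames(m) <- c("time_s", paste0("cell_", pm$order))
    utils::write.csv(m, file.path(dir, paste0("heatmap_", ax, ".csv")))
  }
  pa <- population_amplitude(traces, n_stim = ex$protocol$n_pulses)
  utils::write.csv(data.frame(time_s = pa$time, amplitude_hz = pa$amplitude),
                   file.path(dir, "population_amplitude.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Current vs. rate half-decay ratio across the excitatory population
#'
#' For each excitatory (non-OFF) cell, synthesizes the total current and the
#' noiseless f-I-transformed rate, measures both half-decay times
#' numerically, and returns their ratio. The fast ionotropic transient is
#' excluded when locating the slow-current peak (search starts at
#' \code{t_min}).
#'
#' @param pop a \code{ubc_population}.
#' @param protocol a \code{\link{stimulus_protocol}}.
#' @param params the \code{\link{continuum_params}} used to generate
#'   \code{pop}.
#' @param t_min start of the half-decay search window, s.
#' @param t_max model grid extent, s.
#' @return data.frame with per-cell current and rate half-decays and their
#'   ratio.
#' @export
halfdecay_ratios <- function(pop, protocol = stimulus_protocol(),
                             params = attr(pop, "params"),
                             t_min = 0.03, t_max = 150) {
  exc <- pop[pop$class != "off", ]
  grid <- make_time_grid(protocol, t_max = t_max)
  out <- data.frame(cell_id = exc$cell_id, hd_current = NA_real_,
                    hd_rate = NA_real_)
  for (i in seq_len(nrow(exc))) {
    cell <- exc[i, ]
    cur <- synth_current(cell, protocol, grid, params)
    rt <- f_i_transform(cur, cell, params$fi_exponent, params$fi_gain)
    sel <- grid >= t_min
    out$hd_current[i] <- half_decay_time(grid[sel], cur$total[sel])
    out$hd_rate[i] <- half_decay_time(grid[sel], rt$rate[sel],
                                      baseline = cell$baseline_hz)
  }
  out$ratio <- out$hd_current / out$hd_rate
  out
}
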