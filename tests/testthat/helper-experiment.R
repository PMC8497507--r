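# shared fixtures, computed once per test run

.fixture_env <- new.env(parent = emptyenv())

# full default experiment (84 cells, 5 trials); reused by the acceptance
# checks and the population-statistics tests
default_experiment <- function() {
  if (is.null(.fixture_env$ex))
    .fixture_env$ex <- suppressWarnings(simulate_ubc_experiment(seed = 1))
  .fixture_env$ex
}

# constant-rate trace helper
flat_rate <- function(rate_hz, t0 = -5, t1 = 10, n = 500, cell_id = 1) {
  structure(list(time = seq(t0, t1, length.out = n),
                 rate = rep(rate_hz, n), cell_id = cell_id,
                 n_trials = NA_integer_, kind = "model"),
            class = "rate_trace")
}

# rate trace from an arbitrary rate vector on a grid
rate_trace_of <- function(time, rate, cell_id = 1) {
  structure(list(time = time, rate = rate, cell_id = cell_id,
                 n_trials = NA_integer_, kind = "model"),
            class = "rate_trace")
}

# spike_trains object from a list of per-trial spike-time vectors
trains_of <- function(trials, cell_id = 1) {
  df <- data.frame(cell_id = rep(cell_id, sum(lengths(trials))),
                   trial = rep(seq_along(trials), lengths(trials)),
                   time = unlist(trials))
  attr(df, "n_trials") <- length(trials)
  class(df) <- c("spike_trains", "data.frame")
  df
}
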