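# Log-Gaussian fitting, closed-form features, classification.

test_that("adjusted R-squared follows the exact formula", {
  expect_equal(adjusted_r2(1, 20, 3), 1)
  expect_equal(adjusted_r2(0.5, 12, 1), 0.45)
  expect_equal(adjusted_r2(0, 101, 1), 1 - 100 / 99)   # can be negative
  expect_error(adjusted_r2(0.5, 4, 3))
})

test_that("noiseless log-Gaussian is recovered to 0.1% in trace mode", {
  grid <- analysis_grid()
  tr <- rate_trace_of(grid, log_gaussian(grid, 100, 0, 1, baseline = 7))
  bl <- structure(list(mean_hz = 7, sd_hz = 0, mean_isi_s = 1 / 7,
                       window = c(-5, -0.5), silent = FALSE),
                  class = "baseline_stats")
  fit <- fit_log_gaussian(tr, bl)
  expect_true(fit$converged)
  expect_equal(fit$A, 100, tolerance = 1e-3)
  expect_equal(fit$mu, 0, tolerance = 1e-3)
  expect_equal(fit$sigma, 1, tolerance = 1e-3)
  expect_gt(fit$r2_adj, 0.999)
  # predict/coef/residuals methods
  expect_equal(unname(coef(fit)["sigma"]), fit$sigma)
  expect_equal(predict(fit, exp(fit$mu)), fit$baseline + fit$A,
               tolerance = 1e-4)
  expect_lt(max(abs(residuals(fit))), 1e-4)
})

test_that("a flat trace yields a not-applicable fit", {
  grid <- analysis_grid()
  tr <- rate_trace_of(grid, rep(25, length(grid)))
  bl <- structure(list(mean_hz = 25, sd_hz = 0.5, mean_isi_s = 0.04,
                       window = c(-5, -0.5), silent = FALSE),
                  class = "baseline_stats")
  fit <- fit_log_gaussian(tr, bl)
  expect_true(fit$not_applicable)
  expect_equal(fit$A, 0)
  ft <- features_from_fit(fit, 0)
  expect_true(is.na(ft$peak_time))
})

test_that("closed-form features match their definitions and limits", {
  fit <- structure(list(A = 50, mu = 0, sigma = 1.787, baseline = 5,
                        se_A = NA, se_sigma = NA, r2_adj = 1,
                        converged = TRUE, not_applicable = FALSE,
                        at_bounds = FALSE),
                   class = "log_gaussian_fit")
  ft <- features_from_fit(fit, 0.1)
  s <- 1.787 * sqrt(log(2))
  expect_equal(ft$peak_time, 1)
  expect_equal(ft$hw_pt_ratio, 2 * sinh(s))
  expect_lt(abs(ft$hw_pt_ratio - 4.2), 0.01)
  expect_equal(ft$half_decay, exp(s) - 1)
  expect_lt(abs(ft$half_decay - 3.43), 0.01)
  expect_equal(ft$pause, 0.1)
  # narrow-width limit: half-width -> 0, peak time fixed
  fit$sigma <- 1e-4; fit$mu <- log(10)
  ft2 <- features_from_fit(fit, 0)
  expect_equal(ft2$peak_time, 10)
  expect_lt(ft2$half_width, 0.01)
})

test_that("closed-form features agree with a numerical grid oracle", {
  set.seed(11)
  for (i in 1:200) {
    A <- runif(1, 5, 300); mu <- runif(1, log(0.02), log(5))
    sig <- runif(1, 0.3, 3)
    tg <- exp(seq(mu - 4 * sig, mu + 4 * sig, length.out = 40001))
    y <- A * exp(-((log(tg) - mu) / sig)^2)
    ipk <- which.max(y)
    above <- y >= A / 2
    t_lo <- tg[range(which(above))]
    expect_equal(tg[ipk], exp(mu), tolerance = 5e-3)
    expect_equal(t_lo[2] - t_lo[1], 2 * exp(mu) * sinh(sig * sqrt(log(2))),
                 tolerance = 5e-3)
    expect_equal(t_lo[2] - tg[ipk], exp(mu) * (exp(sig * sqrt(log(2))) - 1),
                 tolerance = 5e-3)
  }
})

test_that("fit is scale-equivariant and log-time-shift covariant", {
  grid <- analysis_grid()
  bl0 <- structure(list(mean_hz = 0, sd_hz = 0, mean_isi_s = NA,
                        window = c(-5, -0.5), silent = TRUE),
                   class = "baseline_stats")
  base <- fit_log_gaussian(
    rate_trace_of(grid, log_gaussian(grid, 40, log(0.3), 1.5)), bl0)
  # rate scaling: A scales, mu and sigma unchanged
  sc <- fit_log_gaussian(
    rate_trace_of(grid, 3 * log_gaussian(grid, 40, log(0.3), 1.5)), bl0)
  expect_equal(sc$A, 3 * base$A, tolerance = 1e-3)
  expect_equal(sc$mu, base$mu, tolerance = 1e-3)
  expect_equal(sc$sigma, base$sigma, tolerance = 1e-3)
  # time rescaling t -> 2t: mu shifts by ln 2, sigma and ratio unchanged
  ts <- fit_log_gaussian(
    rate_trace_of(grid, log_gaussian(grid, 40, log(0.6), 1.5)), bl0)
  expect_equal(ts$mu, base$mu + log(2), tolerance = 1e-3)
  expect_equal(ts$sigma, base$sigma, tolerance = 1e-3)
  expect_equal(features_from_fit(ts)$hw_pt_ratio,
               features_from_fit(base)$hw_pt_ratio, tolerance = 1e-3)
})

test_that("count-mode fit recovers generator parameters from 5 noisy trials", {
  # a generator-like cell: A_r = 80 Hz, peak 0.5 s, sigma 1.79
  gm <- make_time_grid(t_max = 120)
  tr <- rate_trace_of(gm, log_gaussian(gm, 80, log(0.5), 1.79, baseline = 10))
  sp <- generate_spikes(tr, n_trials = 5, seed = 9)
  grid <- analysis_grid()
  avg <- average_trials(lapply(ubcontinuum:::split_trials(sp), isi_rate,
                               grid = grid))
  bl <- estimate_baseline(avg, c(min(grid), -0.44), trains = sp)
  fit <- fit_log_gaussian(avg, bl, mask_below = 0.02, trains = sp)
  expect_true(fit$converged)
  expect_equal(fit$A, 80, tolerance = 0.15)
  expect_equal(fit$mu, log(0.5), tolerance = 0.15)
  expect_equal(fit$sigma, 1.79, tolerance = 0.15)
  expect_true(is.finite(fit$se_A) && fit$se_A > 0)
})

test_that("random-effects width pooling shrinks noisy estimates to the center", {
  set.seed(12)
  true_sig <- 1.8
  se <- c(rep(0.1, 10), rep(0.8, 10))
  est <- true_sig + rnorm(20, 0, se)
  pool <- pool_log_widths(est, se)
  expect_equal(pool$mean, true_sig, tolerance = 0.15)
  # noisy estimates move more than precise ones
  d_prec <- mean(abs(pool$shrunk[1:10] - est[1:10]))
  d_noisy <- mean(abs(pool$shrunk[11:20] - est[11:20]))
  expect_gt(d_noisy, d_prec)
  expect_lt(sd(pool$shrunk), sd(est))
})

test_that("classification separates excited, biphasic, suppressed, unresponsive", {
  bl <- structure(list(mean_hz = 40, sd_hz = 2, mean_isi_s = 0.025,
                       window = c(-5, -0.5), silent = FALSE),
                  class = "baseline_stats")
  ft <- function(A, pause, sig_ok = TRUE)
    structure(list(amplitude = A, pause = pause, amp_significant = sig_ok,
                   low_confidence = FALSE, baseline = 40),
              class = "response_features")
  expect_equal(classify_response(ft(50, 0.001), bl), "excited")
  expect_equal(classify_response(ft(50, 0.5), bl), "biphasic")
  expect_equal(classify_response(ft(0, 0.5), bl), "suppressed")
  expect_equal(classify_response(ft(1, 0.001), bl), "unresponsive")
  # insignificant amplitude does not count as excitation
  expect_equal(classify_response(ft(50, 0.5, sig_ok = FALSE), bl),
               "suppressed")
})
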