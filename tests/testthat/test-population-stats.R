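# Population-level statistics: sorting, regressions, soft-plus, KS,
# population amplitude and the shifted power law.

test_that("sorting and normalization follow the two-group rule", {
  grid <- c(seq(-1, -0.01, by = 0.01), exp(seq(log(0.005), log(60),
                                               length.out = 200)))
  mk <- function(id, cls, hd, pz, pk, bl, rate)
    list(feat = data.frame(cell_id = id, class = cls, half_decay_s = hd,
                           pause_s = pz, peak_time_s = pk, baseline_hz = bl),
         tr = rate_trace_of(grid, rate, cell_id = id))
  r_exc <- function(pk) log_gaussian(grid, 50, log(pk), 1.5, baseline = 5)
  r_sup <- function(pz) ifelse(grid > 0 & grid < pz, 0, 40)
  cells <- list(mk(1, "excited", 3, 0, 1, 5, r_exc(1)),
                mk(2, "excited", 0.3, 0, 0.1, 5, r_exc(0.1)),
                mk(3, "suppressed", NA, 0.8, NA, 40, r_sup(0.8)),
                mk(4, "suppressed", NA, 0.4, NA, 40, r_sup(0.4)),
                mk(5, "unresponsive", NA, 0, NA, 10, rep(10, length(grid))))
  feats <- do.call(rbind, lapply(cells, `[[`, "feat"))
  traces <- lapply(cells, `[[`, "tr")
  expect_message(pm <- sort_and_normalize(feats, traces), "excluded")
  expect_equal(pm$order, c(2, 1, 4, 3))
  expect_equal(pm$normalization, c("peak", "peak", "baseline", "baseline"))
  # excited rows peak at 1; suppressed rows sit at 1 at baseline, 0 in pause
  expect_equal(max(pm$log10$matrix[1, ]), 1)
  expect_equal(max(pm$log10$matrix[2, ]), 1)
  sup_row <- pm$log10$matrix[3, ]
  expect_equal(sup_row[pm$log10$time > 0.5], rep(1, sum(pm$log10$time > 0.5)))
  expect_true(all(sup_row[pm$log10$time < 0.35] == 0))
})

test_that("rank regressions recover exact synthetic trends", {
  n <- 40
  pk <- 10^(-1.5 + 0.027 * (seq_len(n) - 1))
  feats <- data.frame(cell_id = seq_len(n), class = "excited",
                      half_decay_s = pk * 3.4, peak_time_s = pk,
                      half_width_s = 4.2 * pk, hw_pt_ratio = 4.2,
                      pause_s = 0, sigma = 1.787, baseline_hz = 10)
  rr <- rank_regressions(feats)
  expect_equal(rr$peak_time$slope, 0.027, tolerance = 1e-10)
  expect_equal(rr$peak_time$intercept, -1.5 - 0.027, tolerance = 1e-8)
  expect_equal(rr$peak_time$r2_adj, 1, tolerance = 1e-10)
  # constant ratio: slope 0, intercept at the ratio
  expect_equal(rr$hw_pt_ratio$slope, 0, tolerance = 1e-10)
  expect_equal(rr$hw_pt_ratio$intercept, 4.2, tolerance = 1e-8)
  expect_error(rank_regressions(feats[1:5, ]), "10")
})

test_that("soft-plus amplitude fit recovers synthetic parameters", {
  set.seed(21)
  x <- 1:70
  y <- 2.3 - log(1 + exp(x / 8)) + rnorm(70, 0, 0.02)
  sf <- fit_softplus_amplitude(y, x)
  expect_true(sf$converged)
  expect_equal(sf$a, 2.3, tolerance = 0.1)
  expect_equal(sf$b, 8, tolerance = 0.1)
  # fitted curve is monotone non-increasing
  expect_true(all(diff(predict(sf, 1:70)) <= 0))
  # near-constant amplitudes: degenerate, b very large
  sf2 <- fit_softplus_amplitude(rep(2, 30) + rnorm(30, 0, 1e-4))
  expect_true(!sf2$converged || sf2$degenerate || sf2$b > 100)
})

test_that("soft-plus fit of the generated population matches its amplitude law", {
  pop <- sample_population(seed = 1)
  exc <- pop[pop$class != "off", ]
  exc <- exc[order(exc$peak_time_s), ]
  sf <- fit_softplus_amplitude(log10(exc$amp_hz))
  expect_true(sf$converged && !sf$degenerate)
  # fitted curve at rank 1 close to the realized maximum amplitude
  expect_equal(10^predict(sf, 1), max(exc$amp_hz), tolerance = 0.3)
  # log-linear tail slope ~ the conservation slope of the continuum
  tail_slope <- diff(predict(sf, c(69, 70)))
  expect_equal(tail_slope, -0.027 * log(10^1), tolerance = 0.25)
})

test_that("KS uniformity test behaves at its extremes and rejects bad input", {
  n <- 50
  exact <- -1.5 + (seq_len(n) - 0.5) / n * 1.863
  ks <- ks_uniformity(exact, c(-1.5, 0.363))
  expect_equal(ks$statistic, 1 / (2 * n), tolerance = 1e-6)
  expect_gt(ks$p_value, 0.99)
  ks0 <- ks_uniformity(rep(0, 30), c(-1.5, 0.363))
  expect_lt(ks0$p_value, 1e-6)
  expect_error(ks_uniformity(c(0, 1), c(-1.5, 0.363)), "range")
  # clearly non-uniform draws are rejected
  set.seed(3)
  ks1 <- ks_uniformity(-1.5 + 1.863 * rbeta(200, 4, 4), c(-1.5, 0.363))
  expect_lt(ks1$p_value, 0.01)
})

test_that("population amplitude is the RMS rate across cells", {
  gr <- seq(0.01, 10, by = 0.01)
  r <- log_gaussian(gr, 50, 0, 1.5)
  m_same <- matrix(rep(r, 5), nrow = 5, byrow = TRUE)
  pa <- population_amplitude(m_same, time = gr, n_stim = 20)
  expect_equal(pa$amplitude, r)             # N identical cells -> r(t)
  m_one <- rbind(r, matrix(0, 3, length(gr)))
  pa1 <- population_amplitude(m_one, time = gr)
  expect_equal(pa1$amplitude, r / 2)        # one active cell among 4
  # invariant to cell order; linear under global scaling
  m_mix <- rbind(r, 2 * r, 0 * r)
  expect_equal(population_amplitude(m_mix[c(3, 1, 2), ], time = gr)$amplitude,
               population_amplitude(m_mix, time = gr)$amplitude)
  expect_equal(population_amplitude(3 * m_mix, time = gr)$amplitude,
               3 * population_amplitude(m_mix, time = gr)$amplitude)
})

test_that("shifted power-law fit is exact on noiseless synthetic curves", {
  gr <- exp(seq(log(0.05), log(40), length.out = 200))
  amps <- lapply(c(10, 20, 40), function(n) {
    structure(list(time = gr, amplitude = 100 * n * (gr + 0.2 * n^0.5)^(-1.5),
                   n_cells = 1, n_stim = n),
              class = "population_amplitude")
  })
  pl <- fit_shifted_powerlaw(amps, t_range = c(0.05, 40))
  expect_equal(pl$C, 100, tolerance = 1e-3)
  expect_equal(pl$t_min, 0.2, tolerance = 1e-3)
  expect_equal(pl$beta, 0.5, tolerance = 1e-3)
  expect_equal(pl$alpha, -1.5, tolerance = 1e-3)
  expect_false(pl$non_decaying)
})

test_that("single-cell tail exponent matches a finite-difference oracle", {
  gr <- exp(seq(log(0.005), log(60), length.out = 500))
  r <- log_gaussian(gr, 100, log(0.05), 1.787)
  pa <- population_amplitude(matrix(r, 1), time = gr, n_stim = 20)
  win <- c(1, 4)
  pl <- fit_shifted_powerlaw(list(pa), t_range = win)
  sel <- gr >= win[1] & gr <= win[2] & r > 0
  oracle <- coef(lm(log(r[sel]) ~ log(gr[sel] + pl$t_min * 20^pl$beta)))[2]
  expect_equal(pl$alpha, unname(oracle), tolerance = 0.05)
})

test_that("population decay exponent is near -1 under exact conservation,
           steeper with the saturating amplitude law", {
  gr <- exp(seq(log(0.005), log(60), length.out = 300))
  mk <- function(tpk, amp) {
    m <- t(vapply(seq_along(tpk), function(i)
      log_gaussian(gr, amp[i], log(tpk[i]), 1.787), numeric(length(gr))))
    lapply(c(10, 20, 40), function(n)
      population_amplitude(m * n / 20, time = gr, n_stim = n))
  }
  # wide idealized continuum (no saturation, exact A x t conservation):
  # squared log-Gaussians against A ~ 1/t integrate to L2 ~ 1/t
  tpk_w <- 10^seq(-2.5, 1.5, length.out = 300)
  pl_c <- fit_shifted_powerlaw(mk(tpk_w, 100 * 0.0316 / tpk_w),
                               t_range = c(0.1, 3))
  expect_equal(pl_c$alpha, -1, tolerance = 0.1)
  # default saturating law over the study's peak-time range
  tpk_s <- 10^seq(-1.5, 0.363, length.out = 300)
  pl_s <- fit_shifted_powerlaw(mk(tpk_s, amplitude_law(tpk_s)),
                               t_range = c(0.1, 3))
  expect_lt(pl_s$alpha, -1)
  # stability across the stimulus counts: refitting each n alone agrees
  amps_s <- mk(tpk_s, amplitude_law(tpk_s))
  alphas <- vapply(amps_s, function(a)
    fit_shifted_powerlaw(list(a), t_range = c(0.1, 3))$alpha, numeric(1))
  expect_lt(max(alphas) - min(alphas), 0.1)
})

test_that("bootstrap over cells yields a finite CI containing the estimate", {
  gr <- exp(seq(log(0.01), log(30), length.out = 150))
  set.seed(31)
  tpk <- 10^runif(40, -1.5, 0.363)
  m <- t(vapply(seq_along(tpk), function(i)
    log_gaussian(gr, amplitude_law(tpk[i]), log(tpk[i]), 1.787),
    numeric(length(gr))))
  pa <- population_amplitude(m, time = gr, n_stim = 20)
  pl <- fit_shifted_powerlaw(list(pa), t_range = c(0.1, 3),
                             cell_matrices = list(m), n_boot = 40, seed = 5)
  expect_true(all(is.finite(pl$alpha_ci95)))
  expect_lt(pl$alpha_ci95[1], pl$alpha)
  expect_gt(pl$alpha_ci95[2], pl$alpha)
})
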