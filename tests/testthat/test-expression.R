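# Latent-gradient transcriptomics: generator, NNMF, factor selection,
# gene ordering. Reduced problem sizes keep the recovery simulations fast.

small_spec <- gradient_spec(n_genes = 300, n_group1 = 20, n_group2 = 20,
                            n_ionotropic = 10, n_cells = 200)

test_that("count generator encodes the gradient in its means", {
  ex <- generate_expression(small_spec, seed = 1)
  expect_true(all(ex$counts >= 0))
  expect_true(all(ex$counts == round(ex$counts)))
  # zero loading -> expression independent of the latent gradient
  nulls <- ex$genes$pathway == "null"
  r_null <- cor(t(log1p(ex$counts[nulls, ][1:50, ])), ex$cells$f)
  expect_lt(mean(abs(r_null)), 0.1)
  # loading w doubles the log-mean across the gradient: e^2x mean ratio
  hi <- ex$cells$f > 0.8; lo <- ex$cells$f < 0.2
  g1 <- ex$genes$pathway == "group1_mGluR"
  ratio <- mean(ex$counts[g1, hi]) / mean(ex$counts[g1, lo])
  expect_equal(log(ratio), 2 * (mean(ex$cells$f[hi]) - mean(ex$cells$f[lo])),
               tolerance = 0.15)
  # inverse gradient: group1 and group2 mean expression anticorrelate
  m1 <- colMeans(ex$counts[g1, ])
  m2 <- colMeans(ex$counts[ex$genes$pathway == "group2_mGluR", ])
  expect_lt(cor(m1, m2), -0.5)
  expect_error(generate_expression(gradient_spec(n_genes = 10, n_group1 = 2,
                                                 n_group2 = 2,
                                                 n_ionotropic = 1,
                                                 b_range = c(40, 50))),
               "overflow")
})

test_that("log transform is the finite non-negative log(1 + x)", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  m <- matrix(c(0, 1, 5, 20), 2)
  expect_true(all(diff(log_transform(m[, 1])) > 0))   # monotone
  expect_error(log_transform(matrix(-1)), "non-negative")
})

test_that("NNMF reconstructs exact low-rank structure and never increases error", {
  set.seed(41)
  w <- runif(30, 0.5, 2); h <- runif(20, 0.5, 2)
  v1 <- outer(w, h)
  fit1 <- nnmf(v1, rank = 1, seed = 1)
  expect_lt(fit1$error, 1e-6)
  expect_true(all(fit1$W >= 0) && all(fit1$H >= 0))
  expect_true(all(diff(fit1$error_trace) <= 1e-12))
  # full rank on a small random matrix: near-zero error
  v2 <- matrix(runif(36, 0.1, 1), 6)
  fit2 <- nnmf(v2, rank = 6, seed = 1, max_iter = 2000, tol = 1e-12)
  expect_lt(fit2$error, 1e-3)
  expect_error(nnmf(matrix(0, 3, 3), 1), "zero")
  expect_error(nnmf(matrix(-1, 2, 2), 1), "non-negative")
})

test_that("a rank-3 NNMF factor tracks the latent gradient", {
  ex <- generate_expression(small_spec, seed = 2)
  lm_ <- log_transform(ex$counts)
  fit <- nnmf(lm_, rank = 3, seed = 1)
  g1 <- ex$genes$gene_id[ex$genes$pathway == "group1_mGluR"]
  sel <- select_gradient_factor(fit, lm_, g1)
  expect_gte(abs(cor(sel$loadings, ex$cells$f, method = "spearman")), 0.9)
  # canonicalization: positive-marker correlation is positive
  expect_gt(cor(sel$loadings, colMeans(lm_[g1, ])), 0)
  # rank-1 model trivially returns factor 1
  fit1 <- nnmf(lm_, rank = 1, seed = 1, max_iter = 50)
  expect_equal(select_gradient_factor(fit1, lm_, g1)$factor, 1)
  # null markers correlate weakly -> warning
  nulls <- ex$genes$gene_id[ex$genes$pathway == "null"][1:20]
  expect_warning(select_gradient_factor(fit, lm_, nulls), "weak")
  expect_error(select_gradient_factor(fit, lm_, "nonexistent_gene"),
               "absent")
})

test_that("latent gradient recovery holds across seeds (median |rho| >= 0.9)", {
  rhos <- vapply(1:7, function(s) {
    ex <- generate_expression(small_spec, seed = s)
    lm_ <- log_transform(ex$counts)
    fit <- nnmf(lm_, rank = 3, seed = s)
    g1 <- ex$genes$gene_id[ex$genes$pathway == "group1_mGluR"]
    sel <- select_gradient_factor(fit, lm_, g1)
    abs(cor(sel$loadings, ex$cells$f, method = "spearman"))
  }, numeric(1))
  expect_gte(median(rhos), 0.9)
})

test_that("gene ordering flags the gradient genes at the extremes", {
  ex <- generate_expression(small_spec, seed = 3)
  lm_ <- log_transform(ex$counts)
  fit <- nnmf(lm_, rank = 3, seed = 1)
  g1 <- ex$genes$gene_id[ex$genes$pathway == "group1_mGluR"]
  sel <- select_gradient_factor(fit, lm_, g1)
  oc <- order_and_correlate(lm_, sel$loadings, top_percent = 0.01)
  # cells sorted by decreasing loading
  expect_true(all(diff(sel$loadings[oc$cell_order]) <= 0))
  # flagged set size: ceil(0.01 * n)
  expect_equal(sum(oc$genes$top_flag), ceiling(0.01 * nrow(oc$genes)))
  # a gene proportional to the loading correlates perfectly
  lm2 <- rbind(lm_, probe = sel$loadings - min(sel$loadings))
  oc2 <- order_and_correlate(lm2, sel$loadings)
  expect_equal(oc2$genes$r[oc2$genes$gene_id == "probe"], 1,
               tolerance = 1e-8)
  # group1 vs null separation in r (one-sided rank-sum)
  path <- ex$genes$pathway[match(oc$genes$gene_id, ex$genes$gene_id)]
  p1 <- wilcox.test(oc$genes$r[path == "group1_mGluR"],
                    oc$genes$r[path == "null"],
                    alternative = "greater")$p.value
  p2 <- wilcox.test(oc$genes$r[path == "group2_mGluR"],
                    oc$genes$r[path == "null"],
                    alternative = "less")$p.value
  expect_lt(p1, 0.01)
  expect_lt(p2, 0.01)
  # zero-variance genes are excluded with a log entry
  lm3 <- rbind(lm_, flat = rep(0, ncol(lm_)))
  oc3 <- order_and_correlate(lm3, sel$loadings)
  expect_true("flat" %in% attr(oc3, "excluded"))
  expect_false("flat" %in% oc3$genes$gene_id)
})
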