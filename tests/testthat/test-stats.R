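# AUC aggregation, nuisance regression and the inference battery

grid <- seq(50, 5, by = -1) / 100

test_that("AUC anchors: constant curve 0.45, linear curve 0.12375, quadrature oracle", {
  expect_equal(auc_sparsity(rep(1, 46), grid), 0.45)
  expect_equal(auc_sparsity(grid, grid), (0.50^2 - 0.05^2) / 2)

  set.seed(20)
  v <- rnorm(46)
  # fine-grid Riemann sum on the piecewise-linear interpolant
  s_asc <- sort(grid)
  fine <- seq(0.05, 0.50, by = 1e-5)
  interp <- approx(s_asc, v[order(grid)], xout = fine)$y
  riemann <- sum((utils::head(interp, -1) + utils::tail(interp, -1)) / 2) * 1e-5
  expect_equal(auc_sparsity(v, grid), riemann, tolerance = 1e-6)

  m <- matrix(rnorm(3 * 46), 3, 46)
  expect_equal(auc_sparsity(m, grid),
               apply(m, 1, auc_sparsity, sparsities = grid))
  expect_error(auc_sparsity(rnorm(10), grid), "mismatch")
})

test_that("mean-connectivity regression removes exactly the linear dependence", {
  set.seed(21)
  mc <- rnorm(20)
  # orthogonal by construction: residualize first
  v_orth <- residuals(lm(rnorm(20) ~ mc)) + 5
  expect_equal(regress_out_mean_connectivity(v_orth, mc), unname(v_orth), tolerance = 1e-10)

  v_perfect <- 2 * mc
  adj <- regress_out_mean_connectivity(v_perfect, mc)
  expect_equal(adj, rep(mean(v_perfect), 20), tolerance = 1e-10)

  v <- rnorm(20)
  adj2 <- regress_out_mean_connectivity(v, mc)
  expect_lt(abs(cov(adj2, mc)), 1e-10)
  expect_equal(mean(adj2), mean(v), tolerance = 1e-12)

  expect_warning(regress_out_mean_connectivity(v, rep(1, 20)), "constant")
})

test_that("one-way ANOVA matches the sums-of-squares decomposition and t^2", {
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(anova_oneway(same)$f, 0)

  a <- c(1.2, 3.1, 0.7, 2.2)
  b <- c(2.5, 4.0, 3.3, 2.8, 3.9)
  two <- anova_oneway(list(a, b))
  t_pooled <- (mean(a) - mean(b)) /
    sqrt((((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / 7) * (1/4 + 1/5))
  expect_equal(two$f, t_pooled^2, tolerance = 1e-12)

  g <- list(c(5, 7, 6, 8, 9), c(3, 2, 4, 3, 5), c(6, 6, 7, 5, 8))
  res <- anova_oneway(g)
  ref <- anova(lm(unlist(g) ~ factor(rep(1:3, each = 5))))  # independent oracle
  expect_equal(res$f, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 12L)

  expect_error(anova_oneway(list(c(1, 1), c(1, 1))), "identical")
})

test_that("permutation test: identical samples give p = 1, exact splits match enumeration", {
  a <- c(1.1, 2.2, 3.3, 4.4)
  r <- permutation_ttest(a, a, n_perm = 500, seed = 1)
  expect_equal(r$t, 0)
  expect_equal(r$p_perm, 1.0)

  set.seed(22)
  x <- rnorm(3, 1); y <- rnorm(3)
  ex <- permutation_ttest(x, y, exact = TRUE)
  expect_equal(ex$n_perm, 20)
  # independent enumeration oracle
  pool <- c(x, y)
  tstat <- function(u, v) {
    sp2 <- (var(u) + var(v)) / 2
    (mean(u) - mean(v)) / sqrt(sp2 * (2 / 3))
  }
  ts <- apply(utils::combn(6, 3), 2, function(idx) tstat(pool[idx], pool[-idx]))
  expect_equal(ex$p_perm, mean(abs(ts) >= abs(tstat(x, y)) - 1e-12), tolerance = 1e-12)

  expect_error(permutation_ttest(c(1, 1), c(1, 1)), "variance")
})

test_that("permutation p is deterministic given a seed and smoothed by +1", {
  set.seed(23)
  a <- rnorm(8); b <- rnorm(8, 1)
  r1 <- permutation_ttest(a, b, n_perm = 300, seed = 5)
  r2 <- permutation_ttest(a, b, n_perm = 300, seed = 5)
  expect_identical(r1, r2)
  expect_gt(r1$p_perm, 0)  # +1 smoothing guarantees p > 0
  expect_equal((r1$p_perm * 301) %% 1, 0, tolerance = 1e-9)
})

test_that("BH-FDR matches the step-up definition", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  set.seed(24)
  p <- runif(50)^2
  expect_equal(fdr_bh(p), p.adjust(p, "BH"), tolerance = 1e-12)
  # adjusted p's are monotone in rank
  expect_true(all(diff(sort(fdr_bh(p))[rank(p, ties.method = "first")][order(p)]) >= 0))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's d matches the pooled-SD formula", {
  expect_equal(cohens_d(c(0, 1, 2), c(-1, 0, 1)), 1)  # means 1 vs 0, both SD 1
  x <- c(2.3, 2.3, 5)
  expect_equal(cohens_d(x, x), 0)
  set.seed(25)
  a <- rnorm(4, 1); b <- rnorm(4)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("Spearman correlation uses midranks and the t approximation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)

  xt <- c(1.0, 2.0, 2.0, 3.0, 4.0, 5.0)  # one tie
  yt <- c(2.1, 1.0, 3.5, 2.9, 5.0, 4.7)
  r <- spearman_cor(xt, yt)
  # brute-force: Pearson on midranks
  expect_equal(r$rho, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman", exact = FALSE))
  expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-6)
  expect_error(spearman_cor(rep(1, 5), x), "constant")
})

test_that("BH keeps the realized false-discovery proportion near q on an 80%-null battery", {
  set.seed(26)
  q <- 0.05
  fdp <- replicate(40, {
    n <- 200; n_alt <- 40
    null_p <- runif(n - n_alt)
    # strong alternatives: p from N(3,1) z tests
    alt_p <- 2 * pnorm(-abs(rnorm(n_alt, mean = 3)))
    p <- c(null_p, alt_p)
    is_null <- c(rep(TRUE, n - n_alt), rep(FALSE, n_alt))
    disc <- fdr_bh(p) <= q
    if (!any(disc)) 0 else sum(disc & is_null) / sum(disc)
  })
  expect_lt(mean(fdp), q + 0.03)
})
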