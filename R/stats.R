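#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integral of metric values over the ascending sparsity axis
#' (0.05..0.50 for the default 46-level grid), collapsing one curve to one
#' scalar per subject (per node, for nodal metrics).
#'
#' @param values Numeric vector (global metric, one value per sparsity) or
#'   N x S matrix (nodal metric, one row per node).
#' @param sparsities Sparsity value for each curve point, same length/order
#'   as `values` columns.
#' @return Scalar, or length-N vector for matrix input.
#' @export
auc_sparsity <- function(values, sparsities) {
  if (is.matrix(values)) {
    if (ncol(values) != length(sparsities)) stop("auc_sparsity: grid length mismatch")
    return(apply(values, 1L, auc_sparsity, sparsities = sparsities))
  }
  if (length(values) != length(sparsities)) stop("auc_sparsity: grid length mismatch")
  if (length(values) < 2L) stop("auc_sparsity: need at least 2 sparsity points")
  ord <- order(sparsities)
  s <- sparsities[ord]
  v <- values[ord]
  sum(diff(s) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Remove linear mean-connectivity dependence from per-subject values
#'
#' Residuals of a single-predictor OLS of `values` on `mean_conn`, pooled
#' across all subjects (group labels deliberately excluded from the nuisance
#' model), plus the grand mean to preserve location.  The output has exactly
#' zero sample covariance with `mean_conn`.
#'
#' @param values Per-subject metric values (e.g. Q-AUC).
#' @param mean_conn Per-subject mean connectivity.
#' @return Adjusted values, same length and location as the input.
#' @export
regress_out_mean_connectivity <- function(values, mean_conn) {
  if (length(values) != length(mean_conn)) stop("length mismatch")
  if (length(values) < 3L) stop("regress_out_mean_connectivity: need at least 3 subjects")
  if (stats::var(mean_conn) == 0) {
    warning("mean connectivity is constant across subjects; values returned unchanged")
    return(values)
  }
  fit <- stats::lm.fit(cbind(1, mean_conn), values)
  unname(fit$residuals) + mean(values)
}

#' One-way ANOVA
#'
#' Classical fixed-effects F test from the sums-of-squares decomposition.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return List with `f`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L)) stop("anova_oneway: every group needs >= 2 values")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(x)
  k <- length(groups)
  grand <- mean(x)
  ss_between <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2, 1.0))
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1.0))
  df_b <- k - 1L
  df_w <- n - k
  if (ss_within == 0 && ss_between == 0) stop("anova_oneway: all values identical; F undefined")
  if (ss_within == 0) stop("anova_oneway: zero within-group variance; F undefined")
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, df_between = df_b, df_within = df_w,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# pooled-variance two-sample t statistic
.pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("pooled t: zero pooled variance")
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Two-sample permutation t test
#'
#' Observed pooled-variance two-sample t, with a two-sided empirical p value
#' from random relabelings: `p = (1 + #{|t_perm| >= |t_obs|}) / (n_perm + 1)`.
#' With `exact = TRUE` all distinct assignments of the pooled sample to the
#' two group sizes are enumerated and the exact tail probability
#' `#{|t_perm| >= |t_obs|} / n_splits` is returned instead.
#'
#' @param a,b Numeric samples (each >= 2 values).
#' @param n_perm Number of random permutations (default 10000).
#' @param seed RNG seed; required for reproducibility of the Monte-Carlo p.
#' @param exact Enumerate all splits instead of sampling.
#' @return List with `t`, `p_perm`, `n_perm`.
#' @export
permutation_ttest <- function(a, b, n_perm = 10000L, seed = 1L, exact = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  t_obs <- .pooled_t(a, b)
  x <- c(a, b)
  na <- length(a)
  n <- length(x)
  tol <- 1e-12
  if (exact) {
    splits <- utils::combn(n, na)
    t_perm <- apply(splits, 2L, function(idx) .pooled_t(x[idx], x[-idx]))
    p <- mean(abs(t_perm) >= abs(t_obs) - tol)
    return(list(t = t_obs, p_perm = p, n_perm = ncol(splits)))
  }
  count <- 0L
  .with_seed(seed, {
    for (r in seq_len(n_perm)) {
      idx <- sample.int(n, na)
      if (abs(.pooled_t(x[idx], x[-idx])) >= abs(t_obs) - tol) count <- count + 1L
    }
  })
  list(t = t_obs, p_perm = (1 + count) / (n_perm + 1), n_perm = n_perm)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment: `p_adj_(i) = min_{j >= i} min(1, p_(j) * m / j)`
#' over the ascending order statistics, mapped back to input order.
#'
#' @param pvals Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values, same order as input.
#' @export
fdr_bh <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("fdr_bh: p values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  ord <- order(pvals)
  adj <- pmin(1, pvals[ord] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Cohen's d with pooled sample SD
#'
#' @param a,b Numeric samples (each >= 2 values).
#' @return `(mean(a) - mean(b)) / s_pooled`.
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) stop("cohens_d: zero pooled standard deviation")
  (mean(a) - mean(b)) / sp
}

#' Spearman rank correlation with t-approximation p value
#'
#' Pearson correlation of average ranks (midranks for ties); two-sided p
#' from `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df.
#'
#' @param x,y Numeric vectors, >= 3 complete pairs.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman_cor: need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("spearman_cor: constant input vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}
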