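# synthetic cohort generator: determinism, planted structure, group effects

test_that("generation is deterministic under a fixed seed", {
  spec <- cohort_spec(n_per_group = c(healthy = 2L), n_nodes = 10L, n_modules = 2L,
                      n_timepoints = 40L, rho_within = 0.6, rho_between = 0,
                      ar_coefficient = 0, seed = 7L)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$timeseries[[1]]$data, c2$timeseries[[1]]$data)
  expect_identical(c1$records, c2$records)
})

test_that("default dimensions match the emulated acquisition (200 volumes, 74 nodes)", {
  spec <- cohort_spec(n_per_group = c(healthy = 1L), seed = 2L)
  co <- generate_cohort(spec)
  expect_equal(dim(co$timeseries[[1]]$data), c(200L, 74L))
  expect_equal(co$timeseries[[1]]$sampling_interval, 3)
})

test_that("empirical correlations converge to the planted values", {
  spec <- cohort_spec(n_per_group = c(healthy = 1L), n_nodes = 8L, n_modules = 2L,
                      n_timepoints = 50000L, rho_within = 0.6, rho_between = 0.05,
                      ar_coefficient = 0, hub_boost = 0, seed = 3L)
  x <- generate_cohort(spec)$timeseries[[1]]$data
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.6), 0.02)   # within-module pair
  expect_lt(abs(cor(x[, 1], x[, 5]) - 0.05), 0.02)  # between-module pair
})

test_that("AR(1) filtering preserves the stationary spatial correlation", {
  spec <- cohort_spec(n_per_group = c(healthy = 1L), n_nodes = 6L, n_modules = 2L,
                      n_timepoints = 50000L, rho_within = 0.5, rho_between = 0.0,
                      ar_coefficient = 0.6, hub_boost = 0, seed = 4L)
  x <- generate_cohort(spec)$timeseries[[1]]$data
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.5), 0.03)
  # temporal autocorrelation at lag 1 ~ phi
  expect_lt(abs(cor(x[-1, 1], x[-nrow(x), 1]) - 0.6), 0.03)
})

test_that("planted partition is contiguous and balanced", {
  expect_equal(planted_partition(8, 2), rep(1:2, each = 4))
  sizes <- table(planted_partition(74, 4))
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), 74)
  expect_error(planted_partition(4, 5), "more modules")
})

test_that("community detection on the noise-free planted covariance recovers the labels", {
  spec <- cohort_spec(n_per_group = c(healthy = 1L), rho_within = 0.6,
                      rho_between = 0.05, ar_coefficient = 0, hub_boost = 0, seed = 7L)
  part <- planted_partition(spec)
  sig <- planted_covariance(spec, "healthy")

  # the spec's single-sparsity example: exact recovery at s = 0.20
  det <- detect_modules(mst_threshold(sig, 0.20), seed = 1L, restarts = 10L)
  expect_equal(outer(det$membership, det$membership, "=="), outer(part, part, "=="))

  # recovery holds over the moderate-sparsity range under lexicographic ties
  stack <- sparsity_sweep(sig)
  for (k in which(stack$sparsities >= 0.10 & stack$sparsities <= 0.25)) {
    d <- detect_modules(stack$graphs[[k]], seed = 1L, restarts = 5L)
    expect_equal(outer(d$membership, d$membership, "=="), outer(part, part, "=="),
                 label = sprintf("partition match at sparsity %.2f", stack$sparsities[k]))
  }
})

test_that("with unbiased tie spreading the planted structure is recoverable even at s = 0.50", {
  # densest case of the recovery invariant: complete within-module blocks plus
  # uniformly spread between-module edges at the forced 50% density
  set.seed(42)
  part <- planted_partition(74, 4)
  same <- outer(part, part, "==")
  n_between <- target_edge_count(0.50, 74) - sum(same & upper.tri(same))
  adj <- matrix(0L, 74, 74)
  adj[same] <- 1L
  diag(adj) <- 0L
  sel <- sample(which(!same & upper.tri(same)), n_between)
  adj[sel] <- 1L
  adj <- pmax(adj, t(adj))
  d <- detect_modules(adj, seed = 1L, restarts = 10L)
  expect_equal(outer(d$membership, d$membership, "=="), same)
})

test_that("clinical covariates respect the group design", {
  spec <- cohort_spec(n_per_group = c(SUDEP = 4L, high_risk = 4L, low_risk = 4L, healthy = 4L),
                      n_nodes = 8L, n_modules = 2L, n_timepoints = 32L, seed = 9L)
  rec <- generate_cohort(spec)$records
  expect_setequal(unique(rec$group), c("SUDEP", "high_risk", "low_risk", "healthy"))
  expect_true(all(rec$gtcs_per_month[rec$group %in% c("low_risk", "healthy")] == 0))
  # risk definition: SUDEP-like and high-risk subjects exceed 3 GTCS/year
  expect_true(all(rec$gtcs_per_month[rec$group %in% c("SUDEP", "high_risk")] > 3 / 12))
  expect_true(all(is.na(rec$ied_count[rec$group == "healthy"])))
  expect_true(all(rec$ied_count[rec$group != "healthy"] >= 0))
})

test_that("non-PSD modularity degradation is rejected naming the group", {
  spec <- cohort_spec(n_per_group = c(SUDEP = 1L, healthy = 1L),
                      n_nodes = 20L, n_modules = 2L, rho_within = 0.6, rho_between = 0.3,
                      group_effects = list(SUDEP = list(delta_rho_between = 0.5)),
                      hub_boost = 0, seed = 1L)
  expect_error(planted_covariance(spec, "SUDEP"), "SUDEP")
  expect_error(generate_cohort(spec), "SUDEP")
})

test_that("participation elevation raises the designated nodes' participation", {
  # sampled realizations (exact tied covariances interact pathologically with
  # the deterministic tie-break; see the vignette's numerical-choices section)
  spec <- cohort_spec(
    n_per_group = c(SUDEP = 1L, healthy = 1L), hub_boost = 0,
    rho_within = 0.5, rho_between = 0.05, ar_coefficient = 0, n_timepoints = 3000L,
    group_effects = list(SUDEP = list(participation_nodes = 1:5, participation_delta = 0.15)),
    seed = 10L
  )
  part <- planted_partition(spec)
  co <- generate_cohort(spec)
  p_of <- function(sid) {
    stack <- sparsity_sweep(wavelet_correlation(co$timeseries[[sid]]$data))
    mean(auc_sparsity(
      sapply(stack$graphs, participation, membership = part)[1:5, ],
      stack$sparsities
    ))
  }
  expect_gt(p_of("SUDEP_01"), p_of("healthy_01"))
})

test_that("hub permutation relocates hubs and produces a negative HDI", {
  spec <- cohort_spec(
    n_per_group = c(low_risk = 1L, healthy = 1L),
    group_effects = list(low_risk = list(hub_permute = TRUE)), seed = 11L
  )
  h_healthy <- hub_prevalence(sparsity_sweep(planted_covariance(spec, "healthy")))
  h_perm <- hub_prevalence(sparsity_sweep(planted_covariance(spec, "low_risk")))
  expect_equal(which(h_healthy$hub_flags), spec$hub_nodes)
  expect_false(any(which(h_perm$hub_flags) %in% spec$hub_nodes))
  expect_lt(hdi(h_perm$mean_degree_per_node, h_healthy$mean_degree_per_node)$slope, 0)
})

test_that("raising delta_rho_between lowers pipeline modularity AUC (sign test)", {
  # paired across levels: the same seed reuses the same Gaussian innovations,
  # so per-subject Q-AUC differences isolate the covariance effect
  deltas <- c(0, 0.035, 0.07)
  n_sub <- 20L
  q_by_level <- sapply(deltas, function(delta) {
    ge <- if (delta > 0) list(SUDEP = list(delta_rho_between = delta)) else list()
    spec <- cohort_spec(n_per_group = c(SUDEP = n_sub), n_nodes = 40L, n_modules = 4L,
                        n_timepoints = 100L, group_effects = ge, seed = 77L)
    co <- generate_cohort(spec)
    sapply(co$timeseries, function(ts) {
      mc <- metric_curves(sparsity_sweep(subject_connectivity(ts)), seed = 1L, restarts = 2L)
      auc_sparsity(mc$modularity, mc$sparsities)
    })
  })
  expect_true(all(diff(colMeans(q_by_level)) < 0))
  for (lv in 1:2) {
    n_down <- sum(q_by_level[, lv + 1] < q_by_level[, lv])
    expect_lt(binom.test(n_down, n_sub, 0.5, alternative = "greater")$p.value, 0.05)
  }
})

test_that("write_cohort emits the pipeline's input formats round-trip", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_per_group = c(SUDEP = 2L, healthy = 2L), n_nodes = 6L,
                      n_modules = 2L, n_timepoints = 24L, seed = 12L)
  co <- generate_cohort(spec)
  write_cohort(co, dir, atlas = synthetic_atlas(spec))
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), 4L)
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  expect_equal(nrow(atlas), 6L)
  ts <- read_timeseries(file.path(dir, "timeseries", "SUDEP_01.tsv"))
  expect_equal(dim(ts$data), c(24L, 6L))
  expect_equal(ts$data, co$timeseries[["SUDEP_01"]]$data, tolerance = 1e-12)
})
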