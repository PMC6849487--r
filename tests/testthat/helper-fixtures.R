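# shared fixtures, all built in code

# two disconnected 4-cliques on 8 nodes
two_cliques <- function() {
  adj <- matrix(0L, 8, 8)
  adj[1:4, 1:4] <- 1L
  adj[5:8, 5:8] <- 1L
  diag(adj) <- 0L
  adj
}

star_graph <- function(n = 5) {
  adj <- matrix(0L, n, n)
  adj[1, 2:n] <- 1L
  adj[2:n, 1] <- 1L
  adj
}

complete_graph <- function(n) {
  adj <- matrix(1L, n, n)
  diag(adj) <- 0L
  adj
}

# random symmetric weight matrix with continuous (tie-free) entries
random_weights <- function(n, seed = 1) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n, -0.2, 0.9), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# random connected binary graph via weight thresholding
random_graph <- function(n, sparsity = 0.4, seed = 1) {
  mst_threshold(random_weights(n, seed), sparsity)
}

# planted 2-module binary graph on n nodes: dense blocks, sparse between
planted_bipartition_graph <- function(n = 12, p_in = 0.9, p_out = 0.1, seed = 3) {
  set.seed(seed)
  half <- n %/% 2
  labels <- rep(1:2, c(half, n - half))
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (labels[i] == labels[j]) p_in else p_out
    adj[i, j] <- adj[j, i] <- as.integer(stats::runif(1) < p)
  }
  list(adj = adj, labels = labels)
}

# independent Q oracle: direct e_mm - a_m^2 summation from edge counts
oracle_q <- function(adj, membership) {
  m2 <- sum(adj)               # 2 * edge count
  if (m2 == 0) return(NA_real_)
  mods <- unique(membership)
  q <- 0
  for (mod in mods) {
    idx <- membership == mod
    e_mm <- sum(adj[idx, idx]) / m2
    a_m <- sum(adj[idx, ]) / m2
    q <- q + e_mm - a_m^2
  }
  q
}

# small pipeline-ready subject list from a generated cohort
cohort_subjects <- function(cohort) {
  lapply(seq_len(nrow(cohort$records)), function(k) {
    sid <- cohort$records$subject_id[k]
    list(ts = cohort$timeseries[[sid]], record = cohort$records[k, , drop = FALSE])
  })
}

# small fast config for pipeline tests
fast_config <- function(..., sparsity_min = 0.20) {
  # sparsity_min raised to 0.20: the default 5% floor is infeasible for the
  # small (10-24 node) graphs used in tests (target edges < N - 1)
  run_config(n_permutations = 200L, restarts = 2L, seed = 11L,
             scope = "subnetwork", sparsity_min = sparsity_min, ...)
}
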