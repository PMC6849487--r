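# run expr with a private RNG state seeded at `seed`, restoring the caller's
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Newman modularity of a partition on a binary graph
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)`, equivalently
#' `sum_m (e_mm - a_m^2)` over modules.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @param membership Integer module label per node.
#' @return Scalar Q.
#' @export
modularity_q <- function(adj, membership) {
  adj <- as.matrix(adj)
  k <- rowSums(adj)
  two_m <- sum(k)
  if (two_m == 0) stop("modularity_q: empty graph")
  same <- outer(membership, membership, "==")
  sum((adj - outer(k, k) / two_m) * same) / two_m
}

#' Community detection by restarted Louvain
#'
#' Runs igraph's Louvain algorithm `restarts` times under a seeded RNG and
#' keeps the partition with maximum Q.  Deterministic given `seed`.  Labels
#' are renumbered contiguously from 1 in order of first appearance.
#'
#' @param adj Binary symmetric adjacency matrix of a connected graph.
#' @param seed RNG seed.
#' @param restarts Number of Louvain restarts (default 20).
#' @return List with `q` (modularity of the best partition), `membership`
#'   (integer labels) and `n_modules`.
#' @export
detect_modules <- function(adj, seed = 1L, restarts = 20L) {
  adj <- as.matrix(adj)
  if (sum(adj) == 0) stop("detect_modules: empty graph")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  best_q <- -Inf
  best_mem <- NULL
  .with_seed(seed, {
    for (r in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(g)
      mem <- igraph::membership(cl)
      q <- modularity_q(adj, mem)
      if (q > best_q) {
        best_q <- q
        best_mem <- mem
      }
    }
  })
  mem <- as.integer(factor(best_mem, levels = unique(best_mem)))
  list(q = best_q, membership = mem, n_modules = max(mem))
}

#' Participation coefficient
#'
#' Guimera-Amaral `P_i = 1 - sum_m (k_im / k_i)^2`: 0 when all of a node's
#' edges stay in its own module, approaching `1 - 1/M` when spread evenly
#' over M modules.  Zero-degree nodes get P = 0 by convention.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @param membership Integer module label per node (every node labeled).
#' @return Numeric vector of length N in `[0, 1]`.
#' @export
participation <- function(adj, membership) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  if (length(membership) != n || anyNA(membership)) {
    stop("participation: membership must label every node")
  }
  k <- rowSums(adj)
  mods <- sort(unique(membership))
  # k_im: edges from node i into module m
  kim <- vapply(mods, function(m) rowSums(adj[, membership == m, drop = FALSE]), numeric(n))
  p <- 1 - rowSums((kim / pmax(k, 1))^2)
  p[k == 0] <- 0
  p
}

#' Degree centrality
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return Integer vector of node degrees (row sums).
#' @export
degree_centrality <- function(adj) {
  as.integer(rowSums(as.matrix(adj)))
}

#' Metric curves across a sparsity stack
#'
#' Computes, for every graph in the stack: modularity Q (with the partition
#' re-detected at each sparsity from that sparsity's own graph),
#' participation of every node against that same partition, and degree
#' centrality.
#'
#' @param stack A `graph_stack`.
#' @param seed RNG seed for community detection (per-sparsity seeds are
#'   derived deterministically).
#' @param restarts Louvain restarts per graph.
#' @return A `metric_curves` list: `sparsities`, `modularity` (numeric
#'   vector), `participation` and `degree` (N x S matrices), `partitions`
#'   (list of memberships), `subject_id`.
#' @export
metric_curves <- function(stack, seed = 1L, restarts = 20L) {
  stopifnot(inherits(stack, "graph_stack"))
  S <- length(stack$graphs)
  n <- nrow(stack$graphs[[1]])
  q <- numeric(S)
  part <- matrix(NA_real_, n, S)
  deg <- matrix(NA_integer_, n, S)
  partitions <- vector("list", S)
  for (s in seq_len(S)) {
    adj <- stack$graphs[[s]]
    det <- detect_modules(adj, seed = seed + s - 1L, restarts = restarts)
    q[s] <- det$q
    partitions[[s]] <- det$membership
    part[, s] <- participation(adj, det$membership)
    deg[, s] <- degree_centrality(adj)
  }
  structure(
    list(
      sparsities = stack$sparsities, modularity = q,
      participation = part, degree = deg,
      partitions = partitions, subject_id = stack$subject_id
    ),
    class = "metric_curves"
  )
}

#' Hub flags and hub prevalence from a sparsity stack
#'
#' Averages degree centrality across all sparsities per node, then flags
#' nodes whose mean degree lies strictly more than one sample standard
#' deviation above the mean over nodes.
#'
#' @param stack A `graph_stack`, or an N x S matrix of per-sparsity degrees.
#' @return A `hub_result`: `mean_degree_per_node`, `hub_flags` (logical),
#'   `hub_prevalence` (count), `threshold`, `subject_id`.
#' @export
hub_prevalence <- function(stack) {
  if (inherits(stack, "graph_stack")) {
    deg <- vapply(stack$graphs, function(a) rowSums(as.matrix(a)),
                  numeric(nrow(stack$graphs[[1]])))
    sid <- stack$subject_id
  } else {
    deg <- as.matrix(stack)
    sid <- NA_character_
  }
  mean_deg <- rowMeans(deg)
  thr <- mean(mean_deg) + stats::sd(mean_deg)
  flags <- mean_deg > thr
  structure(
    list(
      mean_degree_per_node = mean_deg,
      hub_flags = flags,
      hub_prevalence = sum(flags),
      threshold = thr,
      subject_id = sid
    ),
    class = "hub_result"
  )
}

#' Hub distribution index (HDI)
#'
#' OLS regression of (subject regional mean degree minus the healthy-group
#' normative mean degree) on the healthy mean degree, one point per region.
#' A negative slope indicates that high-degree regions in the healthy group
#' are low-degree in the subject, i.e. hub reorganization.
#'
#' @param subject_mean_degrees Length-N vector: subject's per-region degree
#'   averaged over sparsities.
#' @param healthy_mean_degrees Length-N vector: healthy-group grand mean
#'   degree per region (over subjects and sparsities).
#' @return List with `slope` and `intercept`.
#' @export
hdi <- function(subject_mean_degrees, healthy_mean_degrees) {
  if (length(subject_mean_degrees) != length(healthy_mean_degrees)) {
    stop("hdi: vectors must have equal length")
  }
  if (stats::var(healthy_mean_degrees) == 0) {
    stop("hdi: healthy mean-degree profile is constant; slope undefined")
  }
  d <- subject_mean_degrees - healthy_mean_degrees
  fit <- stats::lm.fit(cbind(1, healthy_mean_degrees), d)
  list(slope = unname(fit$coefficients[2]), intercept = unname(fit$coefficients[1]))
}
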