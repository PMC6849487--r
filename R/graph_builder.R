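#' Target edge count for a proportional threshold
#'
#' `round(s * N * (N - 1) / 2)` with base R rounding (round-half-to-even).
#'
#' @param sparsity Proportion of node pairs retained.
#' @param n_nodes Number of nodes.
#' @return Integer edge count.
#' @export
target_edge_count <- function(sparsity, n_nodes) {
  as.integer(round(sparsity * n_nodes * (n_nodes - 1) / 2))
}

# Rank all node pairs by descending signed weight, ties by (i, j) node-index
# order, and mark the edges of the maximum-weight spanning tree (Kruskal over
# that same deterministic order, so MST ties break identically).
.edge_ranking <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w))
  i <- row(w)[ut]
  j <- col(w)[ut]
  wt <- w[ut]
  ord <- order(-wt, i, j)
  i <- i[ord]; j <- j[ord]; wt <- wt[ord]
  # union-find for Kruskal maximum spanning tree
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  in_mst <- logical(length(i))
  n_tree <- 0L
  for (e in seq_along(i)) {
    ri <- find(i[e]); rj <- find(j[e])
    if (ri != rj) {
      parent[ri] <- rj
      in_mst[e] <- TRUE
      n_tree <- n_tree + 1L
      if (n_tree == n - 1L) break
    }
  }
  if (n_tree < n - 1L) stop("edge ranking: weight matrix does not yield a connected spanning tree")
  list(i = i, j = j, weight = wt, in_mst = in_mst, n_nodes = n)
}

.adjacency_from_edges <- function(ranking, keep) {
  n <- ranking$n_nodes
  adj <- matrix(0L, n, n)
  ii <- ranking$i[keep]; jj <- ranking$j[keep]
  adj[cbind(ii, jj)] <- 1L
  adj[cbind(jj, ii)] <- 1L
  adj
}

# Selection rule shared by mst_threshold() and sparsity_sweep(): the maximum
# spanning tree is always kept, then the strongest non-tree edges by rank
# until the target count.  Nestedness across sparsities follows directly.
.select_edges <- function(ranking, m_target, sparsity) {
  n <- ranking$n_nodes
  if (m_target < n - 1L) {
    stop(sprintf(
      "sparsity %.2f: target edge count %d is below the connectivity floor N-1 = %d",
      sparsity, m_target, n - 1L
    ))
  }
  keep <- ranking$in_mst
  n_extra <- m_target - (n - 1L)
  if (n_extra > 0L) {
    extra <- which(!ranking$in_mst)[seq_len(n_extra)]
    keep[extra] <- TRUE
  }
  if (any(ranking$weight[keep] <= 0)) {
    message(sprintf(
      "sparsity %.2f: %d non-positive-weight edges included to reach the target count",
      sparsity, sum(ranking$weight[keep] <= 0)
    ))
  }
  keep
}

#' MST-anchored proportional threshold
#'
#' Binarizes a weighted connectivity matrix at a given sparsity.  The
#' maximum-weight spanning tree is included first (guaranteeing a connected
#' graph), then the strongest remaining edges by descending signed weight
#' until `round(s * N(N-1)/2)` edges are present.  Ties in weight are broken
#' by lexicographic (i, j) node order.
#'
#' @param cm A `connectivity_matrix` or symmetric weight matrix.
#' @param sparsity Proportion of node pairs to retain, in (0, 1].
#' @return Binary symmetric N x N adjacency matrix (0/1 integer, zero
#'   diagonal).
#' @export
mst_threshold <- function(cm, sparsity) {
  w <- if (inherits(cm, "connectivity_matrix")) cm$weights else as.matrix(cm)
  stopifnot(sparsity > 0, sparsity <= 1)
  ranking <- .edge_ranking(w)
  m_target <- target_edge_count(sparsity, nrow(w))
  keep <- .select_edges(ranking, m_target, sparsity)
  .adjacency_from_edges(ranking, keep)
}

#' Sparsity grid by integer arithmetic
#'
#' @param max,min,step Sparsity range bounds and decrement (defaults
#'   0.50, 0.05, 0.01 — the 46-level grid).
#' @return Descending numeric vector of sparsities, free of floating-point
#'   drift (generated as integers over 100).
#' @export
sparsity_grid <- function(max = 0.50, min = 0.05, step = 0.01) {
  pmax_i <- round(max * 100); pmin_i <- round(min * 100); pstep_i <- round(step * 100)
  if ((pmax_i - pmin_i) %% pstep_i != 0L) {
    stop("sparsity_grid: (max - min) must be an integer multiple of step")
  }
  seq(pmax_i, pmin_i, by = -pstep_i) / 100
}

#' Threshold a connectivity matrix across the full sparsity sweep
#'
#' Produces the stack of binary graphs, one per sparsity, from 50% down to
#' 5% of node pairs in 1% decrements (46 graphs).  All graphs share one edge
#' ranking, so the stack is nested: every edge present at sparsity s is
#' present at s + 0.01.
#'
#' @param cm A `connectivity_matrix` or symmetric weight matrix.
#' @param sparsities Sparsity grid; defaults to [sparsity_grid()].
#' @return A `graph_stack`: list with `sparsities`, `graphs` (list of binary
#'   adjacencies, same order) and `subject_id`.
#' @export
sparsity_sweep <- function(cm, sparsities = sparsity_grid()) {
  w <- if (inherits(cm, "connectivity_matrix")) cm$weights else as.matrix(cm)
  sid <- if (inherits(cm, "connectivity_matrix")) cm$subject_id else NA_character_
  ranking <- .edge_ranking(w)
  n <- nrow(w)
  graphs <- lapply(sparsities, function(s) {
    keep <- .select_edges(ranking, target_edge_count(s, n), s)
    .adjacency_from_edges(ranking, keep)
  })
  structure(
    list(sparsities = sparsities, graphs = graphs, subject_id = sid),
    class = "graph_stack"
  )
}

#' @export
print.graph_stack <- function(x, ...) {
  cat(sprintf(
    "<graph_stack> subject %s: %d graphs (%d nodes), sparsity %.2f..%.2f\n",
    x$subject_id, length(x$graphs), nrow(x$graphs[[1]]),
    max(x$sparsities), min(x$sparsities)
  ))
  invisible(x)
}

#' Edge list of a sparsity sweep
#'
#' One row per edge of the densest graph, with the weight and the smallest
#' sparsity at which the edge is still retained (the stack is nested, so an
#' edge is present at every sparsity at or above that value); the MST
#' backbone is retained down to the sparsest graph.
#'
#' @param cm Weighted connectivity matrix.
#' @param sparsities Sparsity grid.
#' @return data.frame with columns `i`, `j`, `weight`,
#'   `first_sparsity_present`.
#' @export
edge_table <- function(cm, sparsities = sparsity_grid()) {
  w <- if (inherits(cm, "connectivity_matrix")) cm$weights else as.matrix(cm)
  ranking <- .edge_ranking(w)
  n <- nrow(w)
  s_asc <- sort(sparsities)  # smallest first: first membership = sparsest graph containing edge
  first_s <- rep(NA_real_, length(ranking$i))
  for (s in rev(s_asc)) {  # from densest down
    keep <- .select_edges(ranking, target_edge_count(s, n), s)
    first_s[keep] <- s
  }
  sel <- !is.na(first_s)
  data.frame(
    i = ranking$i[sel], j = ranking$j[sel],
    weight = ranking$weight[sel],
    first_sparsity_present = first_s[sel]
  )
}
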