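#' Construct an ROI time-series object
#'
#' Container for one subject's parcellated BOLD signal: a T x N matrix whose
#' columns are region-of-interest mean time courses.
#'
#' @param data Numeric T x N matrix, T time points (rows) by N nodes.
#' @param subject_id Subject identifier.
#' @param node_labels Optional character vector of length N; defaults to the
#'   matrix column names or `node_1..node_N`.
#' @param sampling_interval Repetition time in seconds (default 3, a typical
#'   EEG-fMRI TR).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, subject_id, node_labels = NULL, sampling_interval = 3) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("roi_timeseries: missing values in time series for subject ", subject_id)
  if (nrow(data) < 16L) {
    stop("roi_timeseries: need at least 16 time points for a level-2 wavelet decomposition, got ", nrow(data))
  }
  if (ncol(data) < 2L) stop("roi_timeseries: need at least 2 nodes")
  if (is.null(node_labels)) {
    node_labels <- colnames(data)
    if (is.null(node_labels)) node_labels <- paste0("node_", seq_len(ncol(data)))
  }
  if (length(node_labels) != ncol(data)) {
    stop("roi_timeseries: node_labels length does not match column count")
  }
  colnames(data) <- node_labels
  structure(
    list(
      subject_id = as.character(subject_id),
      data = data,
      node_labels = as.character(node_labels),
      sampling_interval = as.numeric(sampling_interval)
    ),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf(
    "<roi_timeseries> subject %s: %d volumes x %d nodes, TR = %gs\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$sampling_interval
  ))
  invisible(x)
}

#' Pearson correlation of wavelet coefficients
#'
#' Turns a matrix of per-node scale-2 MODWT detail coefficients into a
#' symmetric N x N connectivity matrix.  By convention the diagonal is stored
#' as 0 and excluded from every downstream computation.
#'
#' @param coeffs T x N coefficient matrix (e.g. from [modwt_scale2()]).
#' @param subject_id Optional subject id; taken from the `subject_id`
#'   attribute of `coeffs` if present.
#' @return A `connectivity_matrix`: list with `weights` (N x N, zero
#'   diagonal), `mean_connectivity` and `subject_id`.
#' @export
wavelet_correlation <- function(coeffs, subject_id = NULL) {
  coeffs <- as.matrix(coeffs)
  if (is.null(subject_id)) {
    subject_id <- attr(coeffs, "subject_id")
    if (is.null(subject_id)) subject_id <- NA_character_
  }
  v <- apply(coeffs, 2L, stats::var)
  if (any(v == 0)) {
    bad <- colnames(coeffs)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("wavelet_correlation: zero-variance coefficient series for node(s): ",
         paste(bad, collapse = ", "))
  }
  w <- stats::cor(coeffs)
  w <- (w + t(w)) / 2    # enforce exact symmetry
  diag(w) <- 0
  cm <- structure(
    list(weights = w, mean_connectivity = NA_real_, subject_id = as.character(subject_id)),
    class = "connectivity_matrix"
  )
  cm$mean_connectivity <- mean_connectivity(cm)
  cm
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix> subject %s: %d nodes, mean connectivity %.4f\n",
    x$subject_id, nrow(x$weights), x$mean_connectivity
  ))
  invisible(x)
}

#' Mean connectivity of a weighted network
#'
#' Mean over nodes of nodal strength: `(1/N) * sum_i sum_{j != i} w_ij`.
#' Used downstream as the nuisance regressor for AUC measures.
#'
#' @param cm A `connectivity_matrix` or plain symmetric weight matrix.
#' @return Scalar mean connectivity.
#' @export
mean_connectivity <- function(cm) {
  w <- if (inherits(cm, "connectivity_matrix")) cm$weights else as.matrix(cm)
  w <- w - diag(diag(w))
  mean(rowSums(w))
}

#' Wavelet connectivity matrix for one subject
#'
#' Convenience wrapper: scale-2 MODWT of every node series followed by
#' [wavelet_correlation()].
#'
#' @inheritParams modwt_scale2
#' @return A `connectivity_matrix`.
#' @export
subject_connectivity <- function(ts, wavelet_family = "d4", boundary = "periodic") {
  wavelet_correlation(modwt_scale2(ts, wavelet_family, boundary))
}

#' Restrict a connectivity matrix to a node subset
#'
#' Subnetwork analysis restricts the *weighted* matrix before thresholding
#' (sparsity is then defined relative to the subnetwork's own pair count),
#' rather than inducing subgraphs of whole-brain thresholded graphs.
#'
#' @param cm A `connectivity_matrix`.
#' @param nodes Integer or logical index of member nodes.
#' @return A `connectivity_matrix` on the selected nodes, with
#'   `mean_connectivity` recomputed on the restricted matrix.
#' @export
restrict_nodes <- function(cm, nodes) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  w <- cm$weights[nodes, nodes, drop = FALSE]
  if (nrow(w) < 2L) stop("restrict_nodes: subnetwork must keep at least 2 nodes")
  out <- structure(
    list(weights = w, mean_connectivity = NA_real_, subject_id = cm$subject_id),
    class = "connectivity_matrix"
  )
  out$mean_connectivity <- mean_connectivity(out)
  out
}
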