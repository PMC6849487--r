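GROUP_LEVELS <- c("SUDEP", "high_risk", "low_risk", "healthy")

#' Specification of a synthetic rs-fMRI cohort
#'
#' Describes a multi-group cohort of AR(1)-autocorrelated Gaussian ROI time
#' series whose stationary spatial covariance is a planted block (modular)
#' correlation matrix, plus clinical covariates.  Defaults emulate the
#' acquisition and design scale of the study the pipeline targets: four
#' groups (8 SUDEP-like, 16 high-risk, 16 low-risk, 16 healthy subjects),
#' 200 volumes at TR = 3 s, 74 regulatory-subnetwork nodes in 4 modules.
#'
#' Group effects (per group, as a named list):
#' \describe{
#'   \item{delta_rho_between}{added to every between-module correlation
#'     (modularity degradation; the affected covariance must remain PSD).}
#'   \item{participation_nodes, participation_delta}{cross-module
#'     correlation added only on the designated nodes' rows/columns
#'     (participation elevation; projected to the nearest PSD correlation
#'     matrix if needed).}
#'   \item{hub_permute}{logical; relocate the planted hub boost to different
#'     nodes (hub-profile reorganization).}
#' }
#'
#' @param n_per_group Named counts per group label (subset of
#'   SUDEP/high_risk/low_risk/healthy).
#' @param n_nodes,n_modules Node and planted module counts.
#' @param n_timepoints Volumes per scan (default 200).
#' @param sampling_interval TR in seconds (default 3).
#' @param rho_within,rho_between Planted within/between-module correlations,
#'   `0 <= rho_between < rho_within < 1`.
#' @param ar_coefficient AR(1) temporal autocorrelation in `[0, 1)`.
#' @param group_effects Named list of per-group effect lists (see Details).
#' @param hub_nodes Baseline hub nodes (default: first node of each module);
#'   their correlations to all other nodes are boosted by `hub_boost` so a
#'   degree-hub profile exists for `hub_permute` to reorganize.
#' @param hub_boost Correlation boost for hub nodes (default 0.15).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = c(SUDEP = 8L, high_risk = 16L, low_risk = 16L, healthy = 16L),
                        n_nodes = 74L, n_modules = 4L,
                        n_timepoints = 200L, sampling_interval = 3,
                        rho_within = 0.40, rho_between = 0.10,
                        ar_coefficient = 0.3,
                        group_effects = list(),
                        hub_nodes = NULL, hub_boost = 0.15,
                        seed = 1L) {
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% GROUP_LEVELS)) {
    stop("cohort_spec: n_per_group must be named with labels from: ",
         paste(GROUP_LEVELS, collapse = ", "))
  }
  stopifnot(
    n_modules >= 1L, n_modules <= n_nodes,
    rho_within >= 0, rho_within < 1,
    rho_between >= 0, rho_between < 1,
    rho_between < rho_within,
    ar_coefficient >= 0, ar_coefficient < 1,
    n_timepoints >= 16L
  )
  if (length(group_effects) && !all(names(group_effects) %in% GROUP_LEVELS)) {
    stop("cohort_spec: group_effects names must be group labels")
  }
  if (is.null(hub_nodes)) {
    part <- planted_partition(n_nodes, n_modules)
    hub_nodes <- match(seq_len(n_modules), part)
  }
  structure(
    list(
      n_per_group = n_per_group, n_nodes = as.integer(n_nodes),
      n_modules = as.integer(n_modules), n_timepoints = as.integer(n_timepoints),
      sampling_interval = sampling_interval,
      rho_within = rho_within, rho_between = rho_between,
      ar_coefficient = ar_coefficient, group_effects = group_effects,
      hub_nodes = as.integer(hub_nodes), hub_boost = hub_boost,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Planted module labels
#'
#' Deterministic contiguous-block assignment; when `n_nodes` is not
#' divisible by `n_modules`, the remainder is distributed one node at a
#' time to the first modules, so block sizes differ by at most 1.
#'
#' @param n_nodes Node count, or a `cohort_spec`.
#' @param n_modules Module count (ignored when a spec is supplied).
#' @return Integer vector of module labels, 1..n_modules.
#' @export
planted_partition <- function(n_nodes, n_modules = NULL) {
  if (inherits(n_nodes, "cohort_spec")) {
    n_modules <- n_nodes$n_modules
    n_nodes <- n_nodes$n_nodes
  }
  if (n_modules > n_nodes) stop("planted_partition: more modules than nodes")
  sizes <- rep(n_nodes %/% n_modules, n_modules)
  rem <- n_nodes %% n_modules
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  rep(seq_len(n_modules), times = sizes)
}

# nearest PSD correlation matrix by eigenvalue clipping + renormalization
.project_psd <- function(sigma, eps = 1e-8) {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) >= eps) return(sigma)
  v <- pmax(e$values, eps)
  s <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(s))
  s / outer(d, d)
}

#' Planted stationary covariance for one group
#'
#' Base block correlation matrix (within/between-module levels), hub boost
#' on the designated hub nodes, then the group's effects.  A
#' `delta_rho_between` that breaks positive semi-definiteness is rejected
#' with a diagnostic naming the group; participation elevation is projected
#' back to the nearest PSD correlation matrix when needed.
#'
#' @param spec A `cohort_spec`.
#' @param group Group label.
#' @return N x N correlation (covariance) matrix.
#' @export
planted_covariance <- function(spec, group = "healthy") {
  stopifnot(inherits(spec, "cohort_spec"))
  part <- planted_partition(spec)
  same <- outer(part, part, "==")
  sigma <- ifelse(same, spec$rho_within, spec$rho_between)
  diag(sigma) <- 1

  hubs <- spec$hub_nodes
  eff <- spec$group_effects[[group]]
  if (isTRUE(eff$hub_permute)) {
    # relocate each hub to the next node within its module (wrapping), so the
    # degree profile decorrelates from the healthy normative profile
    hubs <- vapply(hubs, function(h) {
      mod_nodes <- which(part == part[h])
      mod_nodes[(match(h, mod_nodes)) %% length(mod_nodes) + 1L]
    }, integer(1))
  }
  if (spec$hub_boost > 0 && length(hubs)) {
    boost <- matrix(0, spec$n_nodes, spec$n_nodes)
    boost[hubs, ] <- boost[hubs, ] + spec$hub_boost
    boost[, hubs] <- boost[, hubs] + spec$hub_boost
    boost[hubs, hubs] <- spec$hub_boost  # do not double-count hub-hub pairs
    sigma <- sigma + boost
    diag(sigma) <- 1
    sigma <- pmin(sigma, 0.95)
    diag(sigma) <- 1
    # the row/column boost is an indefinite low-rank perturbation; project
    # back to the nearest PSD correlation matrix (same convention as the
    # participation effect)
    sigma <- .project_psd(sigma)
  }

  if (!is.null(eff$delta_rho_between)) {
    sigma[!same] <- sigma[!same] + eff$delta_rho_between
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      stop(sprintf(
        "planted_covariance: covariance for group '%s' is not positive semi-definite after delta_rho_between = %g (min eigenvalue %.3g)",
        group, eff$delta_rho_between, min(ev)
      ))
    }
  }
  if (!is.null(eff$participation_nodes)) {
    delta <- if (is.null(eff$participation_delta)) 0.1 else eff$participation_delta
    pn <- eff$participation_nodes
    cross <- !same
    bump <- matrix(0, spec$n_nodes, spec$n_nodes)
    bump[pn, ] <- delta
    bump[, pn] <- delta
    bump[pn, pn] <- delta
    sigma <- sigma + bump * cross
    sigma <- .project_psd(sigma)
  }
  sigma <- (sigma + t(sigma)) / 2
  sigma
}

# sample a T x N AR(1) process with stationary spatial covariance sigma
.sample_ar1 <- function(n_t, sigma, phi) {
  n <- nrow(sigma)
  ridge <- 0
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  while (is.null(ch)) {
    ridge <- max(ridge * 10, 1e-10)
    ch <- tryCatch(chol(sigma + diag(ridge, n)), error = function(e) NULL)
    if (ridge > 1e-4) stop("sample_ar1: covariance not factorizable")
  }
  x <- matrix(0, n_t, n)
  x[1, ] <- drop(stats::rnorm(n) %*% ch)
  if (n_t > 1L) {
    scale_innov <- sqrt(1 - phi^2)
    innov <- matrix(stats::rnorm((n_t - 1L) * n), n_t - 1L, n) %*% ch
    for (t in 2:n_t) {
      x[t, ] <- phi * x[t - 1L, ] + scale_innov * innov[t - 1L, ]
    }
  }
  x
}

#' Generate a synthetic cohort
#'
#' Samples one ROI time-series matrix per subject from a zero-mean AR(1)
#' process whose stationary covariance is the group's planted block matrix,
#' plus clinical covariates: GTCS/month is 0 for low-risk and healthy
#' subjects and group-conditional lognormal (floored above 3/year) for
#' SUDEP and high-risk; IED counts are Poisson with a common mean across
#' patient groups and missing for healthy controls.
#'
#' @param spec A `cohort_spec`.
#' @return List with `timeseries` (list of [roi_timeseries()]) and
#'   `records` (data.frame: subject_id, group, gtcs_per_month, ied_count).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$n_per_group)
  sigmas <- lapply(groups, function(g) planted_covariance(spec, g))
  names(sigmas) <- groups
  labels <- paste0("node_", seq_len(spec$n_nodes))
  ts_list <- list()
  rec <- list()
  .with_seed(spec$seed, {
    for (g in groups) {
      for (k in seq_len(spec$n_per_group[[g]])) {
        sid <- sprintf("%s_%02d", g, k)
        x <- .sample_ar1(spec$n_timepoints, sigmas[[g]], spec$ar_coefficient)
        colnames(x) <- labels
        ts_list[[sid]] <- roi_timeseries(x, sid, labels, spec$sampling_interval)
        gtcs <- if (g %in% c("SUDEP", "high_risk")) {
          0.25 + stats::rlnorm(1, meanlog = log(1), sdlog = 0.9)
        } else 0
        ied <- if (g == "healthy") NA_integer_ else stats::rpois(1, lambda = 15)
        rec[[sid]] <- data.frame(
          subject_id = sid, group = g,
          gtcs_per_month = gtcs, ied_count = ied,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  list(timeseries = ts_list, records = records)
}

#' Synthetic atlas for a generated cohort
#'
#' One row per node; `lobe` records the planted module and every node is a
#' subnetwork member (the generator plays the role of the already-restricted
#' regulatory network).
#'
#' @param spec A `cohort_spec`.
#' @return data.frame: node_id, label, lobe, subnetwork_member.
#' @export
synthetic_atlas <- function(spec) {
  part <- planted_partition(spec)
  data.frame(
    node_id = seq_len(spec$n_nodes),
    label = paste0("node_", seq_len(spec$n_nodes)),
    lobe = paste0("module_", part),
    subnetwork_member = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Atlas table for the 246-region parcellation with the regulatory flags
#'
#' A synthetic stand-in for the study atlas: 246 regions over 7 lobes, with
#' the regulatory-subnetwork membership flags distributed as in the source
#' selection — medial/orbito-frontal cortex (12), insula (12), cingulate
#' (14), and the full subcortical lobe: amygdala + hippocampus (8), basal
#' ganglia (12) and thalamus (16) — 74 members in total.  Region labels are
#' synthetic placeholders, not the parcellation's own names.
#'
#' @return data.frame: node_id, label, lobe, subnetwork_member.
#' @export
regulatory_atlas <- function() {
  # subcortical nuclei broken out by structure so the membership counts are
  # visible in the table (4 amygdala + 4 hippocampus + 12 basal ganglia +
  # 16 thalamus alongside 12 frontal + 12 insular + 14 cingulate = 74)
  lobes <- c(frontal = 64L, temporal = 40L, parietal = 42L, insular = 12L,
             cingulate = 14L, occipital = 38L, amygdala = 4L,
             hippocampus = 4L, basal_ganglia = 12L, thalamus = 16L)
  flagged <- c(frontal = 12L, temporal = 0L, parietal = 0L, insular = 12L,
               cingulate = 14L, occipital = 0L, amygdala = 4L,
               hippocampus = 4L, basal_ganglia = 12L, thalamus = 16L)
  lobe <- rep(names(lobes), times = lobes)
  member <- unlist(lapply(names(lobes), function(l) {
    m <- logical(lobes[[l]])
    m[seq_len(flagged[[l]])] <- TRUE
    m
  }), use.names = FALSE)
  data.frame(
    node_id = seq_along(lobe),
    label = paste0(lobe, "_", stats::ave(seq_along(lobe), lobe, FUN = seq_along)),
    lobe = lobe,
    subnetwork_member = member,
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' One TSV per subject (header row = node labels), a manifest TSV
#' (subject_id, group, gtcs_per_month, ied_count) and an atlas TSV.
#'
#' @param cohort Output of [generate_cohort()].
#' @param atlas Atlas data.frame; defaults to a synthetic atlas matching the
#'   node count.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, atlas = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  for (ts in cohort$timeseries) {
    utils::write.table(
      ts$data, file.path(ts_dir, paste0(ts$subject_id, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  utils::write.table(
    cohort$records, file.path(dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (is.null(atlas)) {
    n <- ncol(cohort$timeseries[[1]]$data)
    atlas <- data.frame(
      node_id = seq_len(n),
      label = cohort$timeseries[[1]]$node_labels,
      lobe = "synthetic",
      subnetwork_member = TRUE,
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(
    atlas, file.path(dir, "atlas.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
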