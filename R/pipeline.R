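#' Pipeline run configuration
#'
#' @param sparsity_max,sparsity_min,sparsity_step Sparsity sweep bounds and
#'   decrement; defaults 0.50 / 0.05 / 0.01 give the 46-level grid.
#' @param wavelet_family,boundary Wavelet settings, see [modwt()].
#' @param n_permutations Permutations per two-sample test (default 10000).
#' @param restarts Louvain restarts per graph (default 20).
#' @param alpha Nominal significance level gating nodal post-hoc tests.
#' @param seed Integer seed threaded into every stochastic call.
#' @param scope `"subnetwork"`, `"whole_brain"` or `"both"`.
#' @param min_group_size Smallest group size admitted to inference (default 2).
#' @param sampling_interval TR in seconds used when reading time series.
#' @return A `run_config` list.
#' @export
run_config <- function(sparsity_max = 0.50, sparsity_min = 0.05, sparsity_step = 0.01,
                       wavelet_family = "d4", boundary = "periodic",
                       n_permutations = 10000L, restarts = 20L,
                       alpha = 0.05, seed = 42L,
                       scope = c("both", "subnetwork", "whole_brain"),
                       min_group_size = 2L, sampling_interval = 3) {
  scope <- match.arg(scope)
  grid <- sparsity_grid(sparsity_max, sparsity_min, sparsity_step)  # validates the grid
  structure(
    list(
      sparsity_max = sparsity_max, sparsity_min = sparsity_min,
      sparsity_step = sparsity_step, sparsities = grid,
      wavelet_family = wavelet_family, boundary = boundary,
      n_permutations = as.integer(n_permutations), restarts = as.integer(restarts),
      alpha = alpha, seed = as.integer(seed), scope = scope,
      min_group_size = as.integer(min_group_size),
      sampling_interval = sampling_interval
    ),
    class = "run_config"
  )
}

.group_split <- function(values, groups, levels = GROUP_LEVELS) {
  lv <- intersect(levels, unique(groups))
  out <- lapply(lv, function(g) values[groups == g])
  names(out) <- lv
  out
}

.pairwise_contrasts <- function(groups_present) {
  if (length(groups_present) < 2L) return(NULL)
  utils::combn(groups_present, 2L, simplify = FALSE)
}

# global-measure omnibus + post-hoc battery for one measure
.global_inference <- function(values, groups, measure, config, seed_base) {
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  split <- .group_split(values, groups)
  split <- split[vapply(split, length, 1L) >= config$min_group_size]
  if (length(split) < 2L) {
    message("inference skipped for measure '", measure, "': fewer than 2 groups of size >= ",
            config$min_group_size)
    return(list(anova = NULL, posthoc = NULL))
  }
  an <- tryCatch(anova_oneway(split), error = function(e) NULL)
  anova_row <- if (is.null(an)) NULL else data.frame(
    measure = measure, f = an$f, df_between = an$df_between,
    df_within = an$df_within, p = an$p, stringsAsFactors = FALSE
  )
  rows <- list()
  contrasts <- .pairwise_contrasts(names(split))
  for (ci in seq_along(contrasts)) {
    g1 <- contrasts[[ci]][1]; g2 <- contrasts[[ci]][2]
    pt <- tryCatch(
      permutation_ttest(split[[g1]], split[[g2]],
                        n_perm = config$n_permutations,
                        seed = seed_base + ci),
      error = function(e) NULL
    )
    if (is.null(pt)) next
    d <- tryCatch(cohens_d(split[[g1]], split[[g2]]), error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = measure, contrast = paste(g1, "vs", g2),
      t = pt$t, p_perm = pt$p_perm, p_fdr = NA_real_, cohens_d = d,
      stringsAsFactors = FALSE
    )
  }
  list(anova = anova_row, posthoc = if (length(rows)) do.call(rbind, rows) else NULL)
}

# nodal battery: per-node omnibus ANOVA (reported), post-hoc permutation
# tests on every node, BH-FDR across the full node family within each
# contrast (the family is all nodes of the contrast, not the ANOVA-gated
# subset, so null-calibration of the FDR level holds)
.nodal_inference <- function(auc_mat, groups, measure, node_labels, config, seed_base) {
  n_nodes <- nrow(auc_mat)
  anova_p <- rep(NA_real_, n_nodes)
  for (i in seq_len(n_nodes)) {
    split <- .group_split(auc_mat[i, ], groups)
    split <- split[vapply(split, length, 1L) >= config$min_group_size]
    if (length(split) < 2L) next
    anova_p[i] <- tryCatch(anova_oneway(split)$p, error = function(e) NA_real_)
  }
  groups_present <- names(Filter(function(v) v >= config$min_group_size, table(groups)))
  groups_present <- intersect(GROUP_LEVELS, groups_present)
  contrasts <- .pairwise_contrasts(groups_present)
  rows <- list()
  for (ci in seq_along(contrasts)) {
    g1 <- contrasts[[ci]][1]; g2 <- contrasts[[ci]][2]
    a_idx <- groups == g1
    b_idx <- groups == g2
    contrast_rows <- list()
    for (i in seq_len(n_nodes)) {
      pt <- tryCatch(
        permutation_ttest(auc_mat[i, a_idx], auc_mat[i, b_idx],
                          n_perm = config$n_permutations,
                          seed = seed_base + ci * 1000L + i),
        error = function(e) NULL
      )
      if (is.null(pt)) next
      d <- tryCatch(cohens_d(auc_mat[i, a_idx], auc_mat[i, b_idx]),
                    error = function(e) NA_real_)
      contrast_rows[[length(contrast_rows) + 1L]] <- data.frame(
        measure = measure, node = node_labels[i], contrast = paste(g1, "vs", g2),
        anova_p = anova_p[i], t = pt$t, p_perm = pt$p_perm, p_fdr = NA_real_,
        cohens_d = d, stringsAsFactors = FALSE
      )
    }
    if (length(contrast_rows)) {
      tab <- do.call(rbind, contrast_rows)
      tab$p_fdr <- fdr_bh(tab$p_perm)
      rows[[length(rows) + 1L]] <- tab
    }
  }
  anova_tab <- data.frame(
    measure = measure, node = node_labels, anova_p = anova_p,
    stringsAsFactors = FALSE
  )
  list(anova = anova_tab, posthoc = if (length(rows)) do.call(rbind, rows) else NULL)
}

# per-subject metric extraction for one analysis scope
.scope_metrics <- function(subjects, nodes, config) {
  n_sub <- length(subjects)
  first <- TRUE
  out <- list()
  for (k in seq_len(n_sub)) {
    s <- subjects[[k]]
    cm <- s$cm
    if (!is.null(nodes)) cm <- restrict_nodes(cm, nodes)
    stack <- sparsity_sweep(cm, config$sparsities)
    curves <- metric_curves(stack, seed = config$seed, restarts = config$restarts)
    hub <- hub_prevalence(stack)
    if (first) {
      n_nodes <- nrow(cm$weights)
      part_auc <- matrix(NA_real_, n_nodes, n_sub)
      deg_auc <- matrix(NA_real_, n_nodes, n_sub)
      mean_deg <- matrix(NA_real_, n_nodes, n_sub)
      first <- FALSE
    }
    out$q_auc[k] <- auc_sparsity(curves$modularity, config$sparsities)
    part_auc[, k] <- auc_sparsity(curves$participation, config$sparsities)
    deg_auc[, k] <- auc_sparsity(curves$degree, config$sparsities)
    mean_deg[, k] <- rowMeans(curves$degree)
    out$hub_prevalence[k] <- hub$hub_prevalence
    out$mean_conn[k] <- cm$mean_connectivity
  }
  out$part_auc <- part_auc
  out$deg_auc <- deg_auc
  out$mean_deg <- mean_deg
  out$node_labels <- rownames(subjects[[1]]$cm$weights)
  if (is.null(out$node_labels)) out$node_labels <- paste0("node_", seq_len(nrow(part_auc)))
  if (!is.null(nodes)) out$node_labels <- out$node_labels[nodes]
  out
}

# HDI per subject against the healthy normative profile (leave-one-out for
# healthy subjects themselves)
.hdi_per_subject <- function(mean_deg, groups) {
  healthy_idx <- which(groups == "healthy")
  n_sub <- ncol(mean_deg)
  slopes <- rep(NA_real_, n_sub)
  if (length(healthy_idx) < 2L) {
    message("HDI skipped: fewer than 2 healthy subjects for the normative profile")
    return(slopes)
  }
  norm_all <- rowMeans(mean_deg[, healthy_idx, drop = FALSE])
  for (k in seq_len(n_sub)) {
    ref <- if (k %in% healthy_idx) {
      rowMeans(mean_deg[, setdiff(healthy_idx, k), drop = FALSE])
    } else {
      norm_all
    }
    slopes[k] <- tryCatch(hdi(mean_deg[, k], ref)$slope, error = function(e) NA_real_)
  }
  slopes
}

.analyze_scope <- function(subjects, nodes, scope_name, records, config) {
  m <- .scope_metrics(subjects, nodes, config)
  groups <- records$group
  # nuisance regression: mean connectivity out of every AUC-derived measure
  q_auc_adj <- withCallingHandlers(
    regress_out_mean_connectivity(m$q_auc, m$mean_conn),
    warning = function(w) { message("[", scope_name, "] ", conditionMessage(w)); invokeRestart("muffleWarning") }
  )
  adj_mat <- function(mat) {
    if (stats::var(m$mean_conn) == 0) return(mat)
    t(apply(mat, 1L, regress_out_mean_connectivity, mean_conn = m$mean_conn))
  }
  part_auc_adj <- adj_mat(m$part_auc)
  deg_auc_adj <- adj_mat(m$deg_auc)
  hdi_slope <- .hdi_per_subject(m$mean_deg, groups)

  global <- data.frame(
    subject_id = records$subject_id, group = groups,
    mean_connectivity = m$mean_conn,
    q_auc = m$q_auc, q_auc_adj = q_auc_adj,
    hub_prevalence = m$hub_prevalence, hdi_slope = hdi_slope,
    stringsAsFactors = FALSE
  )

  seed0 <- config$seed
  inf_q <- .global_inference(q_auc_adj, groups, "modularity_auc", config, seed0 + 100L)
  inf_hub <- .global_inference(m$hub_prevalence, groups, "hub_prevalence", config, seed0 + 200L)
  # HDI is defined relative to the healthy group: omnibus over patient groups
  patient <- groups != "healthy"
  inf_hdi <- .global_inference(hdi_slope[patient], groups[patient], "hdi_slope",
                               config, seed0 + 300L)
  anova_global <- do.call(rbind, Filter(Negate(is.null),
                                        list(inf_q$anova, inf_hub$anova, inf_hdi$anova)))
  posthoc_global <- do.call(rbind, Filter(Negate(is.null),
                                          list(inf_q$posthoc, inf_hub$posthoc, inf_hdi$posthoc)))

  nod_part <- .nodal_inference(part_auc_adj, groups, "participation_auc",
                               m$node_labels, config, seed0 + 400L)
  nod_deg <- .nodal_inference(deg_auc_adj, groups, "degree_auc",
                              m$node_labels, config, seed0 + 500L)

  # GTCS-frequency correlations over the SUDEP + high-risk pool
  gtcs_tab <- .gtcs_correlations(records, global, part_auc_adj, deg_auc_adj, m$node_labels)

  measures <- data.frame(
    subject_id = records$subject_id,
    modularity_auc = q_auc_adj,
    hub_prevalence = m$hub_prevalence,
    hdi_slope = hdi_slope,
    stringsAsFactors = FALSE
  )
  ied_tab <- check_ied_balance(records, measures)

  list(
    scope = scope_name,
    global = global,
    nodal_auc = list(participation = part_auc_adj, degree = deg_auc_adj,
                     mean_degree = m$mean_deg, node_labels = m$node_labels),
    anova_global = anova_global,
    posthoc_global = posthoc_global,
    anova_nodal = rbind(nod_part$anova, nod_deg$anova),
    posthoc_nodal = rbind(
      if (!is.null(nod_part$posthoc)) nod_part$posthoc,
      if (!is.null(nod_deg$posthoc)) nod_deg$posthoc
    ),
    gtcs_correlations = gtcs_tab,
    ied = ied_tab
  )
}

.gtcs_correlations <- function(records, global, part_auc, deg_auc, node_labels) {
  pool <- records$group %in% c("SUDEP", "high_risk") & !is.na(records$gtcs_per_month)
  if (sum(pool) < 3L) {
    message("GTCS correlations skipped: fewer than 3 SUDEP/high-risk subjects with GTCS data")
    return(NULL)
  }
  gtcs <- records$gtcs_per_month[pool]
  rows <- list()
  add <- function(var, values) {
    r <- tryCatch(spearman_cor(gtcs, values), error = function(e) NULL)
    if (!is.null(r)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = var, rho = r$rho, p = r$p, p_fdr = NA_real_, n = r$n,
        stringsAsFactors = FALSE
      )
    }
  }
  add("modularity_auc", global$q_auc_adj[pool])
  add("hdi_slope", global$hdi_slope[pool])
  add("hub_prevalence", global$hub_prevalence[pool])
  for (i in seq_along(node_labels)) {
    add(paste0("participation_auc:", node_labels[i]), part_auc[i, pool])
    add(paste0("degree_auc:", node_labels[i]), deg_auc[i, pool])
  }
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  tab$p_fdr <- fdr_bh(tab$p)
  tab
}

#' IED-count balance check and correlations
#'
#' Kruskal-Wallis comparison of IED counts across the patient groups, plus
#' Spearman correlations of IED count with each supplied per-subject network
#' measure, BH-FDR corrected over the correlation family.  Degenerate inputs
#' (constant or all-missing IED counts) skip the affected stage with a
#' message rather than failing the run.
#'
#' @param records Manifest data.frame (subject_id, group, ied_count, ...).
#' @param measures data.frame of per-subject measures; first column must be
#'   `subject_id`.
#' @return List with `kruskal` (data.frame or NULL) and `correlations`
#'   (data.frame or NULL).
#' @export
check_ied_balance <- function(records, measures) {
  patient <- records$group %in% c("SUDEP", "high_risk", "low_risk")
  ied <- records$ied_count[patient]
  grp <- records$group[patient]
  if (all(is.na(ied))) {
    message("IED stage skipped: no IED counts available")
    return(list(kruskal = NULL, correlations = NULL))
  }
  ok <- !is.na(ied)
  kw <- tryCatch({
    k <- stats::kruskal.test(ied[ok], factor(grp[ok]))
    data.frame(statistic = unname(k$statistic), df = unname(k$parameter),
               p = k$p.value, stringsAsFactors = FALSE)
  }, error = function(e) {
    message("IED Kruskal-Wallis skipped: ", conditionMessage(e))
    NULL
  })
  rows <- list()
  idx <- match(records$subject_id[patient], measures$subject_id)
  for (v in setdiff(names(measures), "subject_id")) {
    vals <- measures[[v]][idx]
    r <- tryCatch(spearman_cor(ied, vals), error = function(e) {
      message("IED correlation with ", v, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(r)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, rho = r$rho, p = r$p, p_fdr = NA_real_, n = r$n,
        stringsAsFactors = FALSE
      )
    }
  }
  correlations <- NULL
  if (length(rows)) {
    correlations <- do.call(rbind, rows)
    correlations$p_fdr <- fdr_bh(correlations$p)
  }
  list(kruskal = kw, correlations = correlations)
}

#' Run the end-to-end analysis
#'
#' Connectivity -> graph stacks -> metric curves -> AUC -> mean-connectivity
#' regression -> omnibus ANOVA -> post-hoc permutation tests with FDR ->
#' hub statistics -> clinical correlations, for the whole-brain and/or
#' subnetwork scope.  Deterministic given `config$seed`.
#'
#' @param subjects List of `list(ts = roi_timeseries, record = 1-row
#'   manifest data.frame)` as produced by [load_inputs()] (or assembled from
#'   [generate_cohort()]).
#' @param atlas Atlas data.frame defining node order and subnetwork flags.
#' @param config A [run_config()].
#' @return Named list of per-scope result bundles plus `records` and
#'   `config`.
#' @export
run_analysis <- function(subjects, atlas, config = run_config()) {
  stopifnot(length(subjects) >= 1L)
  records <- do.call(rbind, lapply(subjects, `[[`, "record"))
  rownames(records) <- NULL
  if (is.null(records$gtcs_per_month)) records$gtcs_per_month <- NA_real_
  if (is.null(records$ied_count)) records$ied_count <- NA_integer_

  message(sprintf(
    "run_analysis: %d subjects, %d atlas nodes (%d subnetwork members), scope = %s, seed = %d, %d permutations, wavelet = %s/%s",
    length(subjects), nrow(atlas), sum(atlas$subnetwork_member),
    config$scope, config$seed, config$n_permutations,
    config$wavelet_family, config$boundary
  ))
  # wavelet connectivity once per subject, shared across scopes
  for (k in seq_along(subjects)) {
    subjects[[k]]$cm <- subject_connectivity(
      subjects[[k]]$ts, config$wavelet_family, config$boundary
    )
  }
  scopes <- switch(config$scope,
    both = c("whole_brain", "subnetwork"),
    whole_brain = "whole_brain",
    subnetwork = "subnetwork"
  )
  member_nodes <- which(atlas$subnetwork_member)
  out <- list()
  for (sc in scopes) {
    nodes <- if (sc == "subnetwork") member_nodes else NULL
    if (sc == "subnetwork" && length(member_nodes) == nrow(atlas)) {
      # all nodes are members: scope restriction is the identity
      nodes <- NULL
    }
    message("run_analysis: scope '", sc, "'")
    out[[sc]] <- .analyze_scope(subjects, nodes, sc, records, config)
  }
  out$records <- records
  out$config <- config
  class(out) <- "fcgraph_results"
  out
}

#' Write a results bundle as TSV tables plus run metadata
#'
#' @param results Output of [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(tab, name) {
    if (is.null(tab) || !nrow(tab)) return(invisible(NULL))
    utils::write.table(tab, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (sc in intersect(c("whole_brain", "subnetwork"), names(results))) {
    res <- results[[sc]]
    wt(res$global, paste0(sc, "_global_auc.tsv"))
    wt(res$anova_global, paste0(sc, "_anova_global.tsv"))
    wt(res$posthoc_global, paste0(sc, "_posthoc_global.tsv"))
    wt(res$anova_nodal, paste0(sc, "_anova_nodal.tsv"))
    wt(res$posthoc_nodal, paste0(sc, "_posthoc_nodal.tsv"))
    wt(res$gtcs_correlations, paste0(sc, "_gtcs_correlations.tsv"))
    if (!is.null(res$ied$kruskal)) wt(res$ied$kruskal, paste0(sc, "_ied_kruskal.tsv"))
    if (!is.null(res$ied$correlations)) wt(res$ied$correlations, paste0(sc, "_ied_correlations.tsv"))
  }
  cfg <- results$config
  cfg$sparsities <- NULL
  meta <- list(
    package = "fcgraph",
    version = as.character(utils::packageVersion("fcgraph")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = unclass(cfg)
  )
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  meta$config_hash <- unname(tools::md5sum(
    local({ f <- tempfile(); writeLines(json, f); f })
  ))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
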