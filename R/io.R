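# delimiter sniffing: tab if the header contains one, else comma
.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read one subject's ROI time-series file
#'
#' TSV or CSV with a header row of node labels, T rows by N node columns.
#'
#' @param path File path.
#' @param subject_id Subject identifier (defaults to the file name stem).
#' @param sampling_interval TR in seconds.
#' @return A [roi_timeseries()].
#' @export
read_timeseries <- function(path, subject_id = NULL, sampling_interval = 3) {
  if (!file.exists(path)) stop("read_timeseries: file not found: ", path)
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]+$", "", basename(path))
  df <- .read_delim_auto(path)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    stop(sprintf("read_timeseries: non-numeric values in %s, column(s): %s",
                 path, paste(names(df)[bad], collapse = ", ")))
  }
  roi_timeseries(as.matrix(df), subject_id, colnames(df), sampling_interval)
}

#' Read an atlas / node-definition table
#'
#' Expected columns: `node_id`, `label`, `lobe`, `subnetwork_member`
#' (logical or 0/1).
#'
#' @param path File path (TSV or CSV).
#' @return Validated atlas data.frame.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("read_atlas: file not found: ", path)
  atlas <- .read_delim_auto(path)
  need <- c("node_id", "label", "lobe", "subnetwork_member")
  missing_cols <- setdiff(need, names(atlas))
  if (length(missing_cols)) {
    stop("read_atlas: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  atlas$subnetwork_member <- as.logical(atlas$subnetwork_member)
  if (anyDuplicated(atlas$node_id)) stop("read_atlas: duplicate node ids")
  if (!identical(sort(atlas$node_id), seq_len(nrow(atlas)))) {
    stop("read_atlas: node ids must be contiguous 1..N")
  }
  if (sum(atlas$subnetwork_member) < 2L) {
    stop("read_atlas: subnetwork must contain more than 1 member node")
  }
  atlas[order(atlas$node_id), ]
}

#' Read a subject manifest
#'
#' Expected columns: `subject_id`, `group` (SUDEP / high_risk / low_risk /
#' healthy), `gtcs_per_month`, `ied_count`.
#'
#' @param path File path (TSV or CSV).
#' @return Validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("read_manifest: file not found: ", path)
  man <- .read_delim_auto(path)
  need <- c("subject_id", "group")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    stop("read_manifest: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(man$subject_id)) {
    stop("read_manifest: duplicate subject id(s): ",
         paste(unique(man$subject_id[duplicated(man$subject_id)]), collapse = ", "))
  }
  bad_group <- setdiff(unique(man$group), GROUP_LEVELS)
  if (length(bad_group)) {
    stop("read_manifest: unknown group label(s): ", paste(bad_group, collapse = ", "))
  }
  if (is.null(man$gtcs_per_month)) man$gtcs_per_month <- NA_real_
  if (is.null(man$ied_count)) man$ied_count <- NA_integer_
  bad_gtcs <- which(man$group == "low_risk" & !is.na(man$gtcs_per_month) & man$gtcs_per_month != 0)
  if (length(bad_gtcs)) {
    stop("read_manifest: low_risk subjects must have gtcs_per_month = 0; offending subject(s): ",
         paste(man$subject_id[bad_gtcs], collapse = ", "))
  }
  man
}

#' Load and cross-validate all pipeline inputs
#'
#' Subjects whose time-series node count does not match the atlas are
#' excluded with a logged reason; a missing time-series file is an error.
#'
#' @param manifest_path,atlas_path Paths to manifest and atlas tables.
#' @param timeseries_dir Directory containing `<subject_id>.tsv` (or `.csv`)
#'   files.
#' @param sampling_interval TR in seconds.
#' @return List with `subjects` (list of `list(ts =, record =)`), `atlas`,
#'   `excluded` (character).
#' @export
load_inputs <- function(manifest_path, atlas_path, timeseries_dir, sampling_interval = 3) {
  man <- read_manifest(manifest_path)
  atlas <- read_atlas(atlas_path)
  subjects <- list()
  excluded <- character(0)
  for (r in seq_len(nrow(man))) {
    sid <- man$subject_id[r]
    candidates <- file.path(timeseries_dir, paste0(sid, c(".tsv", ".csv", ".txt")))
    path <- candidates[file.exists(candidates)][1]
    if (is.na(path)) {
      stop("load_inputs: no time-series file for subject ", sid, " in ", timeseries_dir)
    }
    ts <- read_timeseries(path, sid, sampling_interval)
    if (ncol(ts$data) != nrow(atlas)) {
      message(sprintf(
        "load_inputs: excluding subject %s: %d node columns, atlas defines %d",
        sid, ncol(ts$data), nrow(atlas)
      ))
      excluded <- c(excluded, sid)
      next
    }
    subjects[[sid]] <- list(ts = ts, record = man[r, , drop = FALSE])
  }
  list(subjects = subjects, atlas = atlas, excluded = excluded)
}
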