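#' Analyse a cohort of pose files or simulated trials
#'
#' Orchestrates the whole pipeline over many trials: conditioning,
#' endpoint extraction, bout tables, aggression indices and
#' multivariate summaries, plus a run manifest. Inputs may be paths
#' to multi-animal pose CSVs (with per-trial metadata) or in-memory
#' results of [simulate_trial()] / [simulate_cohort()]. An unreadable
#' trial is logged in the manifest and skipped; the call fails only
#' if every trial fails.
#'
#' @param inputs either a character vector of pose CSV paths or a
#'   named list of `simulate_trial()` results.
#' @param meta a [trial_meta()], or a list of one per input (only
#'   for path inputs; simulated trials carry their own).
#' @param config a [stagpose_config()].
#' @param out_dir optional directory; when set, writes
#'   `endpoints.csv`, `bouts.csv`, `indices.csv`,
#'   `index_summary.csv`, `endpoint_summary.csv`, `pca.csv`,
#'   `silhouette.csv` and `manifest.yaml`.
#' @return List: `endpoints`, `bouts`, `indices`, `index_summary`,
#'   `endpoint_summary`, `pca`, `clustering`, `manifest`.
#' @export
analyze_cohort <- function(inputs, meta = NULL,
                           config = stagpose_config(),
                           out_dir = NULL) {
  if (length(inputs) < 1) stop("need at least one input trial")
  from_paths <- is.character(inputs)
  ids <- if (!is.null(names(inputs)) && !from_paths) names(inputs)
  else if (from_paths) sub("\\.csv$", "", basename(inputs))
  else sprintf("trial_%02d", seq_along(inputs))

  status <- character(length(inputs))
  ep_tabs <- list(); bout_tabs <- list()
  for (k in seq_along(inputs)) {
    res <- tryCatch({
      if (from_paths) {
        ds <- read_pose_csv(inputs[[k]])
        mk <- if (inherits(meta, "trial_meta")) meta else meta[[k]]
        if (is.null(mk)) stop("no trial_meta supplied for ", inputs[[k]])
      } else {
        ds <- inputs[[k]]$pose
        mk <- inputs[[k]]$meta
      }
      tp <- condition_pose(ds, mk, config)
      list(ep = trial_endpoints(tp, config, ids[k]),
           bouts = trial_bouts(tp, config, ids[k]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[k] <- paste("skipped:", conditionMessage(res))
    } else {
      status[k] <- "ok"
      ep_tabs[[ids[k]]] <- res$ep
      bout_tabs[[ids[k]]] <- res$bouts
    }
  }
  manifest <- list(
    package = "stagpose",
    version = as.character(utils::packageVersion("stagpose")),
    config = config,
    inputs = data.frame(trial_id = ids,
                        source = if (from_paths) unname(inputs)
                        else "in-memory", status = status))
  if (!length(ep_tabs)) {
    if (!is.null(out_dir)) write_manifest(manifest, out_dir)
    stop("all ", length(inputs), " trials failed; see manifest")
  }
  endpoints <- do.call(rbind, ep_tabs); rownames(endpoints) <- NULL
  bouts <- do.call(rbind, bout_tabs); rownames(bouts) <- NULL
  indices <- build_index_table(endpoints)
  index_summary <- if (nrow(indices)) summarize_indices(indices) else indices
  endpoint_summary <- summarize_endpoints(endpoints)

  m <- endpoint_matrix(endpoints, unit = "pair")
  pca <- NULL; clustering <- NULL
  if (nrow(m) >= 3 && ncol(m) >= 2) {
    pca <- tryCatch(pca_summary(m), error = function(e) NULL)
    clustering <- tryCatch(hclust_summary(m), error = function(e) NULL)
  }
  out <- list(endpoints = endpoints, bouts = bouts, indices = indices,
              index_summary = index_summary,
              endpoint_summary = endpoint_summary,
              matrix = m, pca = pca, clustering = clustering,
              manifest = manifest)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_endpoint_table(endpoints, file.path(out_dir, "endpoints.csv"))
    utils::write.csv(bouts, file.path(out_dir, "bouts.csv"),
                     row.names = FALSE)
    utils::write.csv(indices, file.path(out_dir, "indices.csv"),
                     row.names = FALSE)
    utils::write.csv(index_summary,
                     file.path(out_dir, "index_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(endpoint_summary,
                     file.path(out_dir, "endpoint_summary.csv"),
                     row.names = FALSE)
    if (!is.null(pca)) {
      sc <- data.frame(observation = rownames(pca$scores),
                       group = pca$groups, pca$scores)
      utils::write.csv(sc, file.path(out_dir, "pca.csv"),
                       row.names = FALSE)
    }
    if (!is.null(clustering))
      utils::write.csv(clustering$silhouette,
                       file.path(out_dir, "silhouette.csv"),
                       row.names = FALSE)
    write_manifest(manifest, out_dir)
  }
  out
}

write_manifest <- function(manifest, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  m <- manifest
  m$inputs <- lapply(seq_len(nrow(manifest$inputs)), function(r)
    as.list(manifest$inputs[r, ]))
  yaml::write_yaml(m, file.path(out_dir, "manifest.yaml"))
  invisible(file.path(out_dir, "manifest.yaml"))
}

#' Group summary of endpoint records
#'
#' Mean, standard error of the mean and n per (species, pairing,
#' endpoint) group. The s.e.m. is `sd / sqrt(n)` and is reported
#' missing for singleton groups.
#'
#' @param records long-format endpoint records.
#' @return Data frame: `species`, `pairing`, `endpoint`, `mean`,
#'   `sem`, `n`.
#' @export
summarize_endpoints <- function(records) {
  if (!nrow(records)) stop("need at least one endpoint record")
  key <- interaction(records$species, records$pairing,
                     records$endpoint, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    v <- g$value[!is.na(g$value)]
    data.frame(species = g$species[1], pairing = g$pairing[1],
               endpoint = g$endpoint[1],
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
               else NA_real_,
               n = length(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
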