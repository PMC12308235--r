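#' Assemble an endpoint matrix
#'
#' Pivots long-format endpoint records into an observation x endpoint
#' matrix for multivariate summaries. The default observation unit is
#' the pair-trial: per-individual endpoints are averaged over the two
#' individuals of a trial (pair-symmetric endpoints like contact and
#' interaction are identical for both, so they pass through
#' unchanged). With `unit = "individual"` each individual is a row.
#' Missing cells are imputed by their column median and flagged.
#'
#' @param records long-format endpoint records.
#' @param unit `"pair"` (default) or `"individual"`.
#' @return Numeric matrix with a `groups` attribute (species or
#'   species-pair code per row) and an `imputed` attribute (logical
#'   matrix).
#' @export
endpoint_matrix <- function(records, unit = c("pair", "individual")) {
  unit <- match.arg(unit)
  if (unit == "pair") {
    key <- records$trial_id
    grp_of <- function(g) {
      sp <- sort(g$species[!duplicated(g$individual)])
      paste(sp, collapse = "-")
    }
  } else {
    key <- paste(records$trial_id, records$individual, sep = ":")
    grp_of <- function(g) g$species[1]
  }
  ids <- unique(key)
  eps <- intersect(ENDPOINT_NAMES, unique(records$endpoint))
  m <- matrix(NA_real_, length(ids), length(eps),
              dimnames = list(ids, eps))
  groups <- character(length(ids))
  for (r in seq_along(ids)) {
    g <- records[key == ids[r], ]
    groups[r] <- grp_of(g)
    for (ep in eps) {
      v <- g$value[g$endpoint == ep]
      v <- v[!is.na(v)]
      if (length(v)) m[r, ep] <- mean(v)
    }
  }
  imputed <- is.na(m)
  if (any(imputed)) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
    }
    warning(sum(imputed), " missing endpoint cell(s) imputed by ",
            "column median")
  }
  structure(m, groups = groups, imputed = imputed)
}

# z-score columns, dropping zero-variance ones with a warning
zscore_matrix <- function(m) {
  sds <- apply(m, 2, stats::sd)
  zero <- !is.finite(sds) | sds == 0
  if (any(zero)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(m)[zero], collapse = ", "))
    m <- m[, !zero, drop = FALSE]
  }
  scale(m)
}

#' Principal component summary of an endpoint matrix
#'
#' Columns are z-scored (mean 0, sd 1) before the decomposition so
#' percent-scale and centimetre-scale endpoints contribute equally;
#' zero-variance columns are dropped with a warning.
#'
#' @param m an [endpoint_matrix()] (or any numeric matrix).
#' @param n_components number of components to keep; default all.
#' @return List: `scores` (observations x components), `loadings`
#'   (endpoints x components), `explained_fraction` per component
#'   (non-increasing, sums to at most 1), `groups` carried over from
#'   the matrix.
#' @export
pca_summary <- function(m, n_components = NULL) {
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("PCA needs at least 2 rows and 2 columns")
  z <- zscore_matrix(m)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k_max <- min(nrow(m) - 1L, ncol(z))
  k <- min(n_components %||% k_max, k_max)
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       explained_fraction = expl[seq_len(k)],
       groups = attr(m, "groups"))
}

#' Average-linkage clustering with silhouette assessment
#'
#' Agglomerative hierarchical clustering of the (z-scored) endpoint
#' matrix using the Euclidean metric and average (UPGMA) linkage, the
#' standard configuration for behavioural-endpoint heatmaps.
#' Silhouette widths are computed for every cut `k = 2 ...
#' min(k_max, rows - 1)` as a robustness measure.
#'
#' @param m an [endpoint_matrix()] or numeric matrix.
#' @param scale_cols z-score columns first (default TRUE).
#' @param k_max largest cut evaluated (default 8).
#' @return List: `hclust` (the merge tree), `order` (leaf order),
#'   `cophenetic` (cophenetic distance matrix), `silhouette` (data
#'   frame `k`, `avg_width`), `labels` (list of cut labellings, one
#'   integer vector per k), `groups`.
#' @export
hclust_summary <- function(m, scale_cols = TRUE, k_max = 8L) {
  if (nrow(m) < 2) stop("clustering needs at least 2 rows")
  z <- if (scale_cols) zscore_matrix(m) else m
  d <- stats::dist(z, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  ks <- if (nrow(m) >= 3) seq.int(2L, min(k_max, nrow(m) - 1L))
  else integer(0)
  labels <- list()
  sil <- data.frame(k = integer(0), avg_width = numeric(0))
  for (k in ks) {
    cl <- stats::cutree(hc, k = k)
    labels[[as.character(k)]] <- cl
    sw <- cluster::silhouette(cl, d)
    sil <- rbind(sil, data.frame(k = k,
                                 avg_width = mean(sw[, "sil_width"])))
  }
  list(hclust = hc, order = hc$order,
       cophenetic = as.matrix(stats::cophenetic(hc)),
       silhouette = sil, labels = labels, groups = attr(m, "groups"))
}

#' Pearson correlation of endpoints against morphology
#'
#' Pairwise Pearson correlation matrix of the endpoint columns
#' together with per-observation morphological traits (e.g. mandible
#' length, body length). Zero-variance series yield `NA` entries.
#'
#' @param m an [endpoint_matrix()] or numeric matrix.
#' @param traits numeric vector or data frame of per-row trait
#'   values, aligned to the matrix rows.
#' @return Symmetric correlation matrix with unit diagonal (where
#'   defined).
#' @export
pearson_matrix <- function(m, traits) {
  tr <- as.data.frame(traits)
  if (nrow(tr) != nrow(m))
    stop("traits must align with the matrix rows")
  if (nrow(m) < 3) stop("need at least 3 observations")
  full <- cbind(as.matrix(m), as.matrix(tr))
  suppressWarnings(stats::cor(full, use = "pairwise.complete.obs",
                              method = "pearson"))
}
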