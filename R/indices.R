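#' Pairwise aggression index
#'
#' Normalised difference of a behavioural endpoint between the two
#' members of a dyad: `(x_a - x_b) / (x_a + x_b)`. Antisymmetric in
#' its arguments, bounded in \[-1, 1\] for non-negative endpoint
#' values, and invariant to rescaling both values by the same
#' positive factor. When neither individual expressed the behaviour
#' (`x_a + x_b == 0`) the index is 0 and flagged degenerate.
#'
#' @param x_a,x_b non-negative endpoint values (vectorised).
#' @return Numeric vector of indices with a logical `degenerate`
#'   attribute marking zero-sum pairs.
#' @examples
#' aggression_index(10, 5)    # 1/3
#' aggression_index(7, 0)     # 1
#' @export
aggression_index <- function(x_a, x_b) {
  if (any(x_a < 0, na.rm = TRUE) || any(x_b < 0, na.rm = TRUE))
    stop("endpoint values must be non-negative")
  tot <- x_a + x_b
  deg <- !is.na(tot) & tot == 0
  idx <- ifelse(deg, 0, (x_a - x_b) / tot)
  attr(idx, "degenerate") <- deg
  idx
}

# Endpoint feeding each named aggression index. The relative-distance
# index uses each individual's total distance travelled (relative
# movement distance); see the methods vignette for the rationale.
INDEX_ENDPOINTS <- c(
  extended_mandible = "extended_mandible_pct",
  freezing = "freezing_s",
  relative_distance = "total_distance_cm",
  chasing = "chasing_pct")

#' Build the per-trial aggression-index table
#'
#' For every trial with both individuals' endpoint values present,
#' computes one index per requested endpoint, oriented species A
#' minus species B (the first and second individual of the trial).
#' Trials missing a counterpart value are skipped with a warning.
#'
#' @param records endpoint records from [trial_endpoints()] /
#'   [write_endpoint_table()] (long format).
#' @param indices named character vector mapping index names to
#'   endpoint names; default the four standard aggression indices.
#' @return Data frame: `trial_id`, `pairing`, `species_a`,
#'   `species_b`, `endpoint` (index name), `index`, `degenerate`.
#' @export
build_index_table <- function(records, indices = INDEX_ENDPOINTS) {
  out <- list()
  for (tid in unique(records$trial_id)) {
    tr <- records[records$trial_id == tid, ]
    inds <- unique(tr$individual)
    if (length(inds) != 2) {
      warning("trial ", tid, " lacks two individuals; skipped")
      next
    }
    sp <- vapply(inds, function(i)
      tr$species[tr$individual == i][1], character(1))
    for (nm in names(indices)) {
      ep <- indices[[nm]]
      va <- tr$value[tr$individual == inds[1] & tr$endpoint == ep]
      vb <- tr$value[tr$individual == inds[2] & tr$endpoint == ep]
      if (length(va) != 1 || length(vb) != 1 || is.na(va) || is.na(vb)) {
        warning("trial ", tid, ": endpoint ", ep,
                " missing for one individual; index skipped")
        next
      }
      idx <- aggression_index(va, vb)
      out[[length(out) + 1L]] <- data.frame(
        trial_id = tid, pairing = tr$pairing[1],
        species_a = sp[[1]], species_b = sp[[2]],
        endpoint = nm, index = as.numeric(idx),
        degenerate = attr(idx, "degenerate"))
    }
  }
  if (!length(out))
    return(data.frame(trial_id = character(0), pairing = character(0),
                      species_a = character(0), species_b = character(0),
                      endpoint = character(0), index = numeric(0),
                      degenerate = logical(0)))
  do.call(rbind, out)
}

#' Species-level index summary
#'
#' Aggregates per-trial indices by (species pair, endpoint): mean,
#' standard error of the mean (`sd / sqrt(n)`, `NA` for n = 1) and n.
#' The mean of per-trial indices is reported, not the index of summed
#' endpoints, so each trial contributes equally.
#'
#' @param index_table output of [build_index_table()].
#' @return Data frame: `species_a`, `species_b`, `endpoint`, `mean`,
#'   `sem`, `n`.
#' @export
summarize_indices <- function(index_table) {
  key <- interaction(index_table$species_a, index_table$species_b,
                     index_table$endpoint, drop = TRUE)
  rows <- lapply(split(index_table, key), function(g) {
    data.frame(species_a = g$species_a[1], species_b = g$species_b[1],
               endpoint = g$endpoint[1], mean = mean(g$index),
               sem = if (nrow(g) > 1) stats::sd(g$index) / sqrt(nrow(g))
               else NA_real_,
               n = nrow(g))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
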