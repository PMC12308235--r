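#' Read a multi-animal pose CSV
#'
#' Parses the four-header-row multi-animal coordinate dialect emitted
#' by markerless pose-estimation tools: header rows labelled
#' `scorer`, `individuals`, `bodyparts` and `coords`, then one data
#' row per frame with an `x`, `y`, `likelihood` triplet per
#' (individual, body part). Columns are keyed by their header triplet,
#' never by position, so column order does not affect the parsed
#' content.
#'
#' Non-numeric coordinate cells become missing values with likelihood
#' 0. Frame indices are expected 0-based and contiguous; gaps are
#' reindexed with a warning and the dropped frames become
#' likelihood-0 rows. Files describing a single individual
#' (three-header single-animal dialect) are rejected: dyadic trials
#' always contain two individuals.
#'
#' @param path path to the CSV file.
#' @return An object of class `raw_pose`: a list with `individuals`
#'   (length 2), `bodyparts` (the five canonical parts), `n_frames`,
#'   and numeric arrays `x`, `y`, `likelihood` of dimension
#'   (frame, body part, individual), plus `scorer` and `source_path`.
#' @seealso [write_pose_csv()], [apply_pcutoff()]
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path)) stop("pose file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 4)
    stop("malformed pose file: fewer than 4 header rows in ", path)
  labels <- c("scorer", "individuals", "bodyparts", "coords")
  got <- tolower(trimws(raw[seq_len(4), 1]))
  if (got[2] == "bodyparts" && got[3] == "coords")
    stop("single-animal 3-header pose file (no 'individuals' row): ",
         "this pipeline requires the two-individual multi-animal dialect")
  bad <- which(got != labels)
  if (length(bad))
    stop("malformed header: row ", bad[1], " is labelled '", got[bad[1]],
         "', expected '", labels[bad[1]], "'")
  scorer <- raw[1, 2]
  inds <- trimws(unlist(raw[2, -1], use.names = FALSE))
  parts <- trimws(unlist(raw[3, -1], use.names = FALSE))
  coords <- tolower(trimws(unlist(raw[4, -1], use.names = FALSE)))
  if (!all(coords %in% c("x", "y", "likelihood")))
    stop("malformed header: coords row contains values other than ",
         "x / y / likelihood")
  key <- paste(inds, parts, coords, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (individual, bodypart, coord) column: ",
         gsub("\r", "/", key[duplicated(key)][1]))
  individuals <- unique(inds)
  if (length(individuals) != 2)
    stop("expected exactly 2 individuals, found ", length(individuals),
         ": ", paste(individuals, collapse = ", "))
  bodyparts <- unique(parts)
  missing_parts <- setdiff(BODY_PARTS, bodyparts)
  extra_parts <- setdiff(bodyparts, BODY_PARTS)
  if (length(missing_parts) || length(extra_parts))
    stop("body-part vocabulary mismatch; missing: ",
         paste(missing_parts, collapse = ", "), "; unexpected: ",
         paste(extra_parts, collapse = ", "))
  bodyparts <- BODY_PARTS
  for (ind in individuals)
    for (bp in bodyparts)
      for (cc in c("x", "y", "likelihood"))
        if (!paste(ind, bp, cc, sep = "\r") %in% key)
          stop("incomplete triplet: individual '", ind, "' body part '",
               bp, "' lacks a ", cc, " column")

  dat <- raw[-seq_len(4), , drop = FALSE]
  if (nrow(dat) == 0) stop("empty trial: pose file has zero data rows")
  idx <- suppressWarnings(as.numeric(dat[[1]]))
  if (anyNA(idx)) stop("malformed frame index column (non-numeric)")
  idx <- as.integer(idx)
  n_frames <- max(idx) + 1L
  if (!identical(sort(idx), seq.int(0L, n_frames - 1L))) {
    warning("non-contiguous frame indices reindexed; dropped frames ",
            "become likelihood-0 rows")
  }
  dims <- c(n_frames, length(bodyparts), length(individuals))
  dn <- list(NULL, bodyparts, individuals)
  x <- array(NA_real_, dims, dimnames = dn)
  y <- array(NA_real_, dims, dimnames = dn)
  lik <- array(0, dims, dimnames = dn)
  row_at <- idx + 1L
  for (j in seq_along(key)) {
    vals <- suppressWarnings(as.numeric(dat[[j + 1L]]))
    ind_i <- match(inds[j], individuals)
    bp_i <- match(parts[j], bodyparts)
    switch(coords[j],
           x = {x[cbind(row_at, bp_i, ind_i)] <- vals},
           y = {y[cbind(row_at, bp_i, ind_i)] <- vals},
           likelihood = {
             vals[is.na(vals)] <- 0
             lik[cbind(row_at, bp_i, ind_i)] <- vals
           })
  }
  # a missing coordinate invalidates the sample regardless of its score
  lik[is.na(x) | is.na(y)] <- 0
  if (any(lik < 0 | lik > 1))
    stop("likelihood values outside [0, 1] in ", path)
  structure(list(individuals = individuals, bodyparts = bodyparts,
                 n_frames = n_frames, x = x, y = y, likelihood = lik,
                 scorer = scorer, source_path = path),
            class = "raw_pose")
}

#' Write a multi-animal pose CSV
#'
#' Emits the same four-header-row dialect read by [read_pose_csv()];
#' the round trip is stable on all finite values.
#'
#' @param ds a `raw_pose` object.
#' @param path output path.
#' @param digits significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(ds, path, digits = 10) {
  stopifnot(inherits(ds, "raw_pose"))
  if (ds$n_frames == 0) stop("empty trial: refusing to write zero data rows")
  cols <- expand.grid(coord = c("x", "y", "likelihood"),
                      bp = ds$bodyparts, ind = ds$individuals,
                      stringsAsFactors = FALSE)
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = digits,
                                                  format = "g"))
  body <- vapply(seq_len(nrow(cols)), function(j) {
    v <- switch(cols$coord[j],
                x = ds$x[, cols$bp[j], cols$ind[j]],
                y = ds$y[, cols$bp[j], cols$ind[j]],
                likelihood = ds$likelihood[, cols$bp[j], cols$ind[j]])
    fmt(v)
  }, character(ds$n_frames))
  body <- matrix(body, nrow = ds$n_frames)
  lines <- c(
    paste(c("scorer", rep(ds$scorer %||% "stagpose", nrow(cols))),
          collapse = ","),
    paste(c("individuals", cols$ind), collapse = ","),
    paste(c("bodyparts", cols$bp), collapse = ","),
    paste(c("coords", cols$coord), collapse = ","),
    paste(seq_len(ds$n_frames) - 1L,
          apply(body, 1, paste, collapse = ","), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tidy endpoint table
#'
#' Long-format CSV with one row per (trial, individual, endpoint):
#' columns `trial_id`, `pairing` (intra | inter), `species`,
#' `individual`, `endpoint`, `value`, `units`, `denominator_s` (the
#' valid observation time behind each ratio).
#'
#' @param records a data frame of endpoint records, as produced by
#'   [trial_endpoints()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_endpoint_table <- function(records, path) {
  need <- c("trial_id", "pairing", "species", "individual",
            "endpoint", "value", "units", "denominator_s")
  if (!all(need %in% names(records)))
    stop("endpoint records lack column(s): ",
         paste(setdiff(need, names(records)), collapse = ", "))
  if (!all(records$endpoint %in% ENDPOINT_NAMES))
    stop("unknown endpoint name(s): ",
         paste(setdiff(unique(records$endpoint), ENDPOINT_NAMES),
               collapse = ", "))
  keys <- paste(records$trial_id, records$individual, records$endpoint)
  if (anyDuplicated(keys))
    stop("integrity error: duplicate (trial, individual, endpoint) key: ",
         keys[duplicated(keys)][1])
  utils::write.csv(records[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a tidy endpoint table
#' @param path CSV written by [write_endpoint_table()].
#' @return Data frame of endpoint records.
#' @export
read_endpoint_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read trial metadata from a YAML or JSON config file
#'
#' Accepts any file parseable as YAML (JSON is a YAML subset) holding
#' the [trial_meta()] fields.
#'
#' @param path config file path.
#' @return A `trial_meta` object.
#' @export
read_trial_meta <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(trial_meta)))
  do.call(trial_meta, vals[keep])
}

#' @export
print.raw_pose <- function(x, ...) {
  cat("<raw_pose> ", x$n_frames, " frames, individuals: ",
      paste(x$individuals, collapse = ", "), "\n", sep = "")
  pct <- round(100 * mean(x$likelihood >= 0.6), 1)
  cat("  likelihood >= 0.6 in ", pct, "% of samples\n", sep = "")
  invisible(x)
}
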