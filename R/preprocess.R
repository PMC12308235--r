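#' Apply the likelihood cutoff
#'
#' Marks every keypoint sample whose estimation likelihood falls below
#' the cutoff as missing; samples at or above the cutoff are kept
#' unchanged (the boundary is inclusive-keep).
#'
#' @param ds a `raw_pose` object.
#' @param pcutoff likelihood threshold in \[0, 1\]; default 0.6.
#' @return The `raw_pose` with sub-cutoff coordinates set missing.
#' @examples
#' sim <- simulate_trial(sim_config(duration_s = 4, seed = 1))
#' conditioned <- apply_pcutoff(sim$pose, 0.6)
#' @export
apply_pcutoff <- function(ds, pcutoff = 0.6) {
  stopifnot(inherits(ds, "raw_pose"))
  if (!is.numeric(pcutoff) || length(pcutoff) != 1 ||
      pcutoff < 0 || pcutoff > 1)
    stop("pcutoff must be a single value in [0, 1]")
  drop <- ds$likelihood < pcutoff
  ds$x[drop] <- NA_real_
  ds$y[drop] <- NA_real_
  ds
}

# Linear fill of interior missing runs no longer than max_gap, one
# coordinate series at a time. Leading/trailing gaps never filled.
fill_series <- function(v, max_gap) {
  miss <- is.na(v)
  if (!any(miss) || max_gap < 1) return(v)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    if (r$lengths[k] > max_gap) next
    a <- starts[k] - 1L
    b <- ends[k] + 1L
    if (a < 1L || b > length(v)) next          # edge gap: leave invalid
    n <- r$lengths[k]
    v[starts[k]:ends[k]] <- v[a] + (v[b] - v[a]) * seq_len(n) / (n + 1)
  }
  v
}

#' Interpolate short tracking gaps
#'
#' Runs of at most `max_gap_frames` consecutive missing samples,
#' flanked by valid samples on both sides, are linearly interpolated
#' per coordinate. Longer runs and leading/trailing gaps remain
#' missing: long occlusions (fights frequently occlude mandibles) are
#' too risky to reconstruct.
#'
#' @param ds a `raw_pose` object (normally after [apply_pcutoff()]).
#' @param max_gap_frames maximum fillable gap length in frames;
#'   default 10.
#' @return The `raw_pose` with fillable gaps interpolated.
#' @export
interpolate_gaps <- function(ds, max_gap_frames = 10L) {
  stopifnot(inherits(ds, "raw_pose"))
  if (max_gap_frames < 0) stop("max_gap_frames must be >= 0")
  for (ind in ds$individuals) {
    for (bp in ds$bodyparts) {
      ds$x[, bp, ind] <- fill_series(ds$x[, bp, ind], max_gap_frames)
      ds$y[, bp, ind] <- fill_series(ds$y[, bp, ind], max_gap_frames)
    }
  }
  ds
}

#' Calibrate pixel coordinates to centimetres
#'
#' Divides pixel coordinates by the isotropic imaging scale, producing
#' analysis-ready tracks with a validity mask. Validity is carried
#' through: a frame is valid for a body part iff both its coordinates
#' are present after conditioning.
#'
#' @param ds a `raw_pose` object (after cutoff / interpolation).
#' @param meta a [trial_meta()] object supplying `px_per_cm`.
#' @return An object of class `trial_pose`: `meta`, `individuals`,
#'   `bodyparts`, `n_frames`, arrays `x_cm`, `y_cm` and logical
#'   `valid` of dimension (frame, body part, individual), and
#'   `n_valid`, the per (body part, individual) valid-frame counts.
#' @export
calibrate <- function(ds, meta) {
  stopifnot(inherits(ds, "raw_pose"), inherits(meta, "trial_meta"))
  if (meta$px_per_cm <= 0) stop("px_per_cm must be > 0")
  valid <- !is.na(ds$x) & !is.na(ds$y)
  x_cm <- ds$x / meta$px_per_cm
  y_cm <- ds$y / meta$px_per_cm
  structure(list(meta = meta, individuals = ds$individuals,
                 bodyparts = ds$bodyparts, n_frames = ds$n_frames,
                 x_cm = x_cm, y_cm = y_cm, valid = valid,
                 n_valid = apply(valid, c(2, 3), sum)),
            class = "trial_pose")
}

#' Condition a raw pose dataset end to end
#'
#' Convenience wrapper: likelihood cutoff, optional rolling-median
#' smoothing, gap interpolation, calibration.
#'
#' @param ds a `raw_pose`.
#' @param meta a [trial_meta()].
#' @param config a [stagpose_config()] list.
#' @return A `trial_pose`.
#' @export
condition_pose <- function(ds, meta, config = stagpose_config()) {
  ds <- apply_pcutoff(ds, config$pcutoff)
  if (isTRUE(config$smooth)) ds <- smooth_pose(ds, window = 3L)
  ds <- interpolate_gaps(ds, config$max_gap_frames)
  calibrate(ds, meta)
}

#' Rolling-median smoothing of keypoint tracks
#'
#' Optional window-3 median filter applied per coordinate series; off
#' by default since per-frame jitter is already small relative to the
#' proximity thresholds.
#'
#' @param ds a `raw_pose`.
#' @param window odd window length.
#' @return The smoothed `raw_pose`.
#' @export
smooth_pose <- function(ds, window = 3L) {
  stopifnot(inherits(ds, "raw_pose"), window %% 2 == 1)
  med <- function(v) {
    if (all(is.na(v)) || length(v) < window) return(v)
    out <- stats::runmed(ifelse(is.na(v), stats::median(v, na.rm = TRUE), v),
                         k = window, endrule = "keep")
    out[is.na(v)] <- NA_real_
    out
  }
  for (ind in ds$individuals) {
    for (bp in ds$bodyparts) {
      ds$x[, bp, ind] <- med(ds$x[, bp, ind])
      ds$y[, bp, ind] <- med(ds$y[, bp, ind])
    }
  }
  ds
}

#' @export
print.trial_pose <- function(x, ...) {
  cat("<trial_pose> ", x$n_frames, " frames @ ", x$meta$fps, " fps; ",
      "arena ", x$meta$arena_w_cm, " x ", x$meta$arena_h_cm, " cm\n",
      sep = "")
  cat("  valid samples: ",
      round(100 * mean(x$valid), 1), "%\n", sep = "")
  invisible(x)
}
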