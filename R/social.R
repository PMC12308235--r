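new_distance_series <- function(d_cm, valid, definition, fps) {
  d_cm[!valid] <- NA_real_
  structure(list(d_cm = d_cm, valid = valid, definition = definition,
                 fps = fps), class = "distance_series")
}

part_xy <- function(pose, individual, part) {
  cbind(pose$x_cm[, part, individual], pose$y_cm[, part, individual])
}

pair_dist <- function(a, b) sqrt(rowSums((a - b)^2))

#' Mandible gape series
#'
#' Per-frame Euclidean distance between the left and right mandible of
#' one individual; the basis of the extended-mandible display
#' endpoint. Invalid wherever either mandible is invalid.
#'
#' @param pose a `trial_pose`.
#' @param individual individual label.
#' @return A `distance_series` (fields `d_cm`, `valid`, `definition`,
#'   `fps`).
#' @export
mandible_gape <- function(pose, individual) {
  stopifnot(inherits(pose, "trial_pose"))
  if (!individual %in% pose$individuals)
    stop("unknown individual: ", individual)
  if (!all(c("left_mandible", "right_mandible") %in% pose$bodyparts))
    stop("pose schema lacks mandible body parts")
  d <- pair_dist(part_xy(pose, individual, "left_mandible"),
                 part_xy(pose, individual, "right_mandible"))
  v <- pose$valid[, "left_mandible", individual] &
    pose$valid[, "right_mandible", individual]
  new_distance_series(d, v, "gape", pose$meta$fps)
}

#' Cross-individual mandible proximity series
#'
#' Per-frame minimum over the four mandible-to-mandible pairs of the
#' two individuals; the fighting proxy. Invalid when no cross pair has
#' both keypoints valid. Symmetric in its arguments.
#'
#' @param pose a `trial_pose`.
#' @param ind_i,ind_j the two individual labels (must differ).
#' @return A `distance_series` tagged `"contact"`.
#' @export
mandible_contact_series <- function(pose, ind_i = pose$individuals[1],
                                    ind_j = pose$individuals[2]) {
  stopifnot(inherits(pose, "trial_pose"))
  if (identical(ind_i, ind_j)) stop("ind_i and ind_j must differ")
  min_pair_series(pose, ind_i, ind_j,
                  parts_i = c("left_mandible", "right_mandible"),
                  parts_j = c("left_mandible", "right_mandible"),
                  definition = "contact")
}

#' Chasing proximity series (directional)
#'
#' Per-frame distance from the chaser's labrum to the chased
#' individual's abdomen — the pursuit proxy. Directional:
#' `chase_series(pose, i, j)` and `chase_series(pose, j, i)` are
#' distinct series.
#'
#' @param pose a `trial_pose`.
#' @param chaser,chased individual labels (must differ).
#' @return A `distance_series` tagged `"chase"`.
#' @export
chase_series <- function(pose, chaser, chased) {
  stopifnot(inherits(pose, "trial_pose"))
  if (identical(chaser, chased)) stop("chaser and chased must differ")
  for (ind in c(chaser, chased))
    if (!ind %in% pose$individuals) stop("unknown individual: ", ind)
  d <- pair_dist(part_xy(pose, chaser, "labrum"),
                 part_xy(pose, chased, "abdomen"))
  v <- pose$valid[, "labrum", chaser] & pose$valid[, "abdomen", chased]
  new_distance_series(d, v, "chase", pose$meta$fps)
}

#' Inter-beetle interaction series
#'
#' Per-frame minimum distance over all 25 cross-individual body-part
#' pairs. Unlike mandible contact (mandibles only), interaction uses
#' the full skeleton.
#'
#' @inheritParams mandible_contact_series
#' @return A `distance_series` tagged `"interaction"`.
#' @export
interaction_series <- function(pose, ind_i = pose$individuals[1],
                               ind_j = pose$individuals[2]) {
  stopifnot(inherits(pose, "trial_pose"))
  if (identical(ind_i, ind_j)) stop("ind_i and ind_j must differ")
  min_pair_series(pose, ind_i, ind_j,
                  parts_i = pose$bodyparts, parts_j = pose$bodyparts,
                  definition = "interaction")
}

# Minimum distance over the cross product of two part sets, ignoring
# pairs with an invalid member; invalid where no pair is available.
min_pair_series <- function(pose, ind_i, ind_j, parts_i, parts_j,
                            definition) {
  for (ind in c(ind_i, ind_j))
    if (!ind %in% pose$individuals) stop("unknown individual: ", ind)
  n <- pose$n_frames
  best <- rep(Inf, n)
  for (pi in parts_i) {
    ai <- part_xy(pose, ind_i, pi)
    vi <- pose$valid[, pi, ind_i]
    for (pj in parts_j) {
      ok <- vi & pose$valid[, pj, ind_j]
      if (!any(ok)) next
      d <- pair_dist(ai, part_xy(pose, ind_j, pj))
      upd <- ok & d < best
      best[upd] <- d[upd]
    }
  }
  valid <- is.finite(best)
  best[!valid] <- NA_real_
  new_distance_series(best, valid, definition, pose$meta$fps)
}

#' Bouts from a boolean predicate series
#'
#' Extracts the maximal runs of TRUE frames (bouts). Runs separated by
#' at most `merge_gap_frames` FALSE frames are merged; merged runs
#' shorter than `min_bout_frames` are dropped. Missing values break
#' runs like FALSE frames.
#'
#' @param mask logical per-frame predicate (NA treated as FALSE).
#' @param fps frames per second.
#' @param merge_gap_frames gap tolerance in frames (default 0: no
#'   debouncing).
#' @param min_bout_frames minimum bout length in frames (default 1).
#' @return An object of class `bout_series`: the cleaned `mask`, a
#'   data frame `bouts` with 1-based inclusive `start_frame`,
#'   `end_frame` and `n_frames`, plus `fps` and `longest_s` (0 when
#'   no bout survives).
#' @export
bouts_from_mask <- function(mask, fps, merge_gap_frames = 0L,
                            min_bout_frames = 1L) {
  if (merge_gap_frames < 0) stop("merge_gap_frames must be >= 0")
  if (min_bout_frames < 1) stop("min_bout_frames must be >= 1")
  m <- as.logical(mask)
  m[is.na(m)] <- FALSE
  runs <- rle(m)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ti <- which(runs$values)
  bouts <- data.frame(start_frame = integer(0), end_frame = integer(0))
  if (length(ti)) {
    cur_s <- starts[ti[1]]
    cur_e <- ends[ti[1]]
    for (k in ti[-1]) {
      if (starts[k] - cur_e - 1L <= merge_gap_frames) {
        cur_e <- ends[k]
      } else {
        bouts <- rbind(bouts, data.frame(start_frame = cur_s,
                                         end_frame = cur_e))
        cur_s <- starts[k]
        cur_e <- ends[k]
      }
    }
    bouts <- rbind(bouts, data.frame(start_frame = cur_s,
                                     end_frame = cur_e))
  }
  if (nrow(bouts)) {
    bouts$n_frames <- bouts$end_frame - bouts$start_frame + 1L
    bouts <- bouts[bouts$n_frames >= min_bout_frames, , drop = FALSE]
    rownames(bouts) <- NULL
  } else {
    bouts$n_frames <- integer(0)
  }
  clean <- rep(FALSE, length(m))
  for (r in seq_len(nrow(bouts)))
    clean[bouts$start_frame[r]:bouts$end_frame[r]] <- TRUE
  structure(list(mask = clean, bouts = bouts, fps = fps,
                 longest_s = if (nrow(bouts)) max(bouts$n_frames) / fps
                 else 0),
            class = "bout_series")
}

# Shared ratio + longest-bout summary of a thresholded distance
# series. Frames invalid for the series are excluded from numerator
# and denominator; the predicate uses a strict inequality in the
# stated direction.
threshold_endpoints <- function(s, thr_cm, direction = c("below", "above"),
                                merge_gap_frames = 0L,
                                min_bout_frames = 1L) {
  stopifnot(inherits(s, "distance_series"))
  if (thr_cm <= 0) stop("threshold must be > 0")
  direction <- match.arg(direction)
  nv <- sum(s$valid)
  if (nv == 0)
    return(list(pct = NA_real_, longest_s = NA_real_, valid_s = 0,
                bouts = NULL, mask = rep(FALSE, length(s$d_cm))))
  hit <- if (direction == "below") s$d_cm < thr_cm else s$d_cm > thr_cm
  hit[!s$valid] <- FALSE
  bs <- bouts_from_mask(hit, s$fps, merge_gap_frames, min_bout_frames)
  list(pct = 100 * sum(bs$mask) / nv,
       longest_s = bs$longest_s,
       valid_s = nv / s$fps,
       bouts = bs,
       mask = bs$mask)
}

#' Extended-mandible endpoints
#'
#' A frame counts as an extended-mandible display when the gape
#' strictly exceeds the threshold (default 0.5 cm). Returns the
#' percent of valid frames extended and the longest extension bout.
#'
#' @param g a gape `distance_series` from [mandible_gape()].
#' @param thr_cm extension threshold in cm.
#' @param merge_gap_frames,min_bout_frames bout debouncing, see
#'   [bouts_from_mask()].
#' @return List with `pct`, `longest_s`, `valid_s`, `bouts`, `mask`;
#'   `pct` and `longest_s` are `NA` when no frame is valid.
#' @export
extended_mandible_ratio <- function(g, thr_cm = 0.5,
                                    merge_gap_frames = 0L,
                                    min_bout_frames = 1L) {
  threshold_endpoints(g, thr_cm, "above", merge_gap_frames,
                      min_bout_frames)
}

#' Mandible-contact endpoints
#'
#' A frame counts as mandible contact when the cross-individual
#' mandible minimum distance is strictly below the threshold
#' (default 3 cm).
#'
#' @param s a contact `distance_series` from
#'   [mandible_contact_series()].
#' @inheritParams extended_mandible_ratio
#' @return As [extended_mandible_ratio()].
#' @export
contact_endpoints <- function(s, thr_cm = 3.0, merge_gap_frames = 0L,
                              min_bout_frames = 1L) {
  threshold_endpoints(s, thr_cm, "below", merge_gap_frames,
                      min_bout_frames)
}

#' Chasing endpoints
#'
#' A frame counts as chasing when the labrum-to-abdomen proximity is
#' strictly below the threshold. With one series the result is
#' directional; passing both directions yields the pair-level
#' endpoint, the per-frame OR of the two directional predicates (a
#' frame is pair-chasing when either individual is chasing the
#' other). For the pair-level denominator a frame is valid when
#' either direction is observable.
#'
#' @param s a chase `distance_series` from [chase_series()].
#' @param s_rev optional reverse-direction series for the pair-level
#'   endpoint.
#' @inheritParams extended_mandible_ratio
#' @return As [extended_mandible_ratio()].
#' @export
chasing_endpoints <- function(s, thr_cm = 3.0, s_rev = NULL,
                              merge_gap_frames = 0L,
                              min_bout_frames = 1L) {
  if (is.null(s_rev))
    return(threshold_endpoints(s, thr_cm, "below", merge_gap_frames,
                               min_bout_frames))
  stopifnot(inherits(s, "distance_series"),
            inherits(s_rev, "distance_series"))
  valid <- s$valid | s_rev$valid
  hit <- (s$valid & s$d_cm < thr_cm) | (s_rev$valid & s_rev$d_cm < thr_cm)
  hit[!valid] <- FALSE
  comb <- new_distance_series(ifelse(hit, 0, thr_cm + 1), valid,
                              "chase_pair", s$fps)
  threshold_endpoints(comb, thr_cm, "below", merge_gap_frames,
                      min_bout_frames)
}

#' Interaction endpoints
#'
#' A frame counts as inter-beetle interaction when the minimum
#' distance over all cross-individual body-part pairs is strictly
#' below the threshold.
#'
#' @param s an interaction `distance_series` from
#'   [interaction_series()].
#' @inheritParams extended_mandible_ratio
#' @return As [extended_mandible_ratio()].
#' @export
interaction_endpoints <- function(s, thr_cm = 3.0, merge_gap_frames = 0L,
                                  min_bout_frames = 1L) {
  threshold_endpoints(s, thr_cm, "below", merge_gap_frames,
                      min_bout_frames)
}
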