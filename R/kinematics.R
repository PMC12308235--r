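#' Locomotion reference point of an individual
#'
#' The per-frame point used for all locomotor endpoints: the scutellum
#' (thorax centre, the most stable landmark of the skeleton). Where
#' the scutellum is invalid the centroid of the remaining valid body
#' parts is used; where no part is valid the frame is invalid.
#'
#' @param pose a `trial_pose`.
#' @param individual individual label.
#' @param part preferred landmark; default `"scutellum"`.
#' @return A list with per-frame `x`, `y` (cm) and logical `valid`.
#' @export
reference_point <- function(pose, individual, part = "scutellum") {
  stopifnot(inherits(pose, "trial_pose"))
  if (!individual %in% pose$individuals)
    stop("unknown individual: ", individual)
  if (!part %in% pose$bodyparts) stop("unknown body part: ", part)
  x <- pose$x_cm[, part, individual]
  y <- pose$y_cm[, part, individual]
  need <- !pose$valid[, part, individual]
  if (any(need)) {
    vm <- pose$valid[, , individual]
    xs <- pose$x_cm[, , individual]
    ys <- pose$y_cm[, , individual]
    nv <- rowSums(vm)
    cx <- rowSums(xs * vm, na.rm = TRUE) / nv
    cy <- rowSums(ys * vm, na.rm = TRUE) / nv
    x[need] <- cx[need]
    y[need] <- cy[need]
  }
  valid <- is.finite(x) & is.finite(y)
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  list(x = x, y = y, valid = valid)
}

#' Total distance travelled
#'
#' Sum of Euclidean displacements between consecutive valid frames of
#' the reference track. A pair of valid frames separated by invalid
#' frames contributes the straight-line displacement between the
#' flanking frames only when the gap does not exceed
#' `max_gap_frames`; longer gaps contribute nothing.
#'
#' @param ref a reference track from [reference_point()].
#' @param max_gap_frames longest bridgeable invalid run.
#' @return Distance in cm, or `NA` when fewer than 2 valid frames
#'   exist (the endpoint is undefined, not zero).
#' @export
total_distance <- function(ref, max_gap_frames = 10L) {
  vi <- which(ref$valid)
  if (length(vi) < 2) return(NA_real_)
  step <- diff(vi)
  d <- sqrt(diff(ref$x[vi])^2 + diff(ref$y[vi])^2)
  sum(d[step - 1L <= max_gap_frames])
}

#' Average speed
#'
#' Total distance divided by the valid observation time: the summed
#' duration of the frame intervals that contribute to
#' [total_distance()].
#'
#' @inheritParams total_distance
#' @param fps frames per second.
#' @return Speed in cm/s, or `NA` when undefined.
#' @export
average_speed <- function(ref, fps, max_gap_frames = 10L) {
  vi <- which(ref$valid)
  if (length(vi) < 2) return(NA_real_)
  step <- diff(vi)
  keep <- step - 1L <= max_gap_frames
  if (!any(keep)) return(NA_real_)
  d <- sqrt(diff(ref$x[vi])^2 + diff(ref$y[vi])^2)
  sum(d[keep]) / (sum(step[keep]) / fps)
}

#' Instantaneous speed series
#'
#' Frame-to-frame speed of the reference track; element `t` is the
#' speed between frames `t` and `t + 1`, valid only when both frames
#' are valid.
#'
#' @inheritParams average_speed
#' @return An object of class `speed_series`: `speed_cm_s`, logical
#'   `valid` (both length frames - 1) and `fps`.
#' @export
speed_series <- function(ref, fps) {
  n <- length(ref$x)
  if (n < 2) stop("need at least 2 frames for a speed series")
  sp <- sqrt(diff(ref$x)^2 + diff(ref$y)^2) * fps
  valid <- ref$valid[-n] & ref$valid[-1]
  sp[!valid] <- NA_real_
  structure(list(speed_cm_s = sp, valid = valid, fps = fps),
            class = "speed_series")
}

#' Classify frames into freezing / normal / rapid movement
#'
#' Per-frame partition of instantaneous speed: below `freeze_thr`
#' is freezing, above `rapid_thr` is rapid, otherwise normal. Time in
#' each class is the frame count divided by fps, so the three classes
#' always partition the valid observation time exactly.
#'
#' @param sp a [speed_series()].
#' @param freeze_thr freezing cutoff in cm/s (default 0.1).
#' @param rapid_thr rapid-movement cutoff in cm/s (default 2).
#' @return A list: `labels` (factor with levels freezing / normal /
#'   rapid / invalid), and `freezing_s`, `normal_s`, `rapid_s`,
#'   `valid_s` durations in seconds.
#' @export
classify_movement <- function(sp, freeze_thr = 0.1, rapid_thr = 2.0) {
  stopifnot(inherits(sp, "speed_series"))
  if (!(freeze_thr >= 0 && freeze_thr < rapid_thr))
    stop("need 0 <= freeze_thr < rapid_thr")
  lab <- rep("invalid", length(sp$speed_cm_s))
  v <- sp$valid
  lab[v & sp$speed_cm_s < freeze_thr] <- "freezing"
  lab[v & sp$speed_cm_s > rapid_thr] <- "rapid"
  lab[v & lab == "invalid"] <- "normal"
  lab <- factor(lab, levels = c("freezing", "normal", "rapid", "invalid"))
  n <- table(lab)
  list(labels = lab,
       freezing_s = as.numeric(n[["freezing"]]) / sp$fps,
       normal_s = as.numeric(n[["normal"]]) / sp$fps,
       rapid_s = as.numeric(n[["rapid"]]) / sp$fps,
       valid_s = sum(v) / sp$fps)
}

#' Thigmotaxis ratio
#'
#' Percentage of valid frames in which the reference point lies within
#' `band_cm` of the arena boundary rectangle. The arena is assumed
#' axis-aligned with the image; `origin_cm` allows an offset
#' rectangle. Points on or beyond a wall count as thigmotactic.
#'
#' @inheritParams total_distance
#' @param meta a [trial_meta()] for the arena dimensions.
#' @param band_cm boundary band width in cm (default 1.5, about one
#'   beetle body-width).
#' @param origin_cm arena top-left corner in calibrated coordinates.
#' @return Percent of valid frames, or `NA` with no valid frames.
#' @export
thigmotaxis_ratio <- function(ref, meta, band_cm = 1.5,
                              origin_cm = c(0, 0)) {
  stopifnot(inherits(meta, "trial_meta"))
  if (!(band_cm > 0 && band_cm < min(meta$arena_w_cm, meta$arena_h_cm) / 2))
    stop("band_cm must be in (0, min(arena)/2)")
  v <- ref$valid
  if (!any(v)) return(NA_real_)
  dx <- pmin(ref$x - origin_cm[1], origin_cm[1] + meta$arena_w_cm - ref$x)
  dy <- pmin(ref$y - origin_cm[2], origin_cm[2] + meta$arena_h_cm - ref$y)
  wall_dist <- pmin(dx, dy)
  100 * sum(wall_dist[v] <= band_cm) / sum(v)
}
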