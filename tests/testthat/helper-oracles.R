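# Independent brute-force oracles: every function here recomputes a
# pipeline quantity with plain per-frame loops / naive scans, sharing
# no code with the package implementation.

oracle_total_distance <- function(x, y, valid, max_gap) {
  vi <- which(valid)
  if (length(vi) < 2) return(NA_real_)
  tot <- 0
  for (k in 2:length(vi)) {
    a <- vi[k - 1]; b <- vi[k]
    if (b - a - 1 <= max_gap)
      tot <- tot + sqrt((x[b] - x[a])^2 + (y[b] - y[a])^2)
  }
  tot
}

oracle_average_speed <- function(x, y, valid, fps, max_gap) {
  vi <- which(valid)
  if (length(vi) < 2) return(NA_real_)
  tot <- 0; tsec <- 0
  for (k in 2:length(vi)) {
    a <- vi[k - 1]; b <- vi[k]
    if (b - a - 1 <= max_gap) {
      tot <- tot + sqrt((x[b] - x[a])^2 + (y[b] - y[a])^2)
      tsec <- tsec + (b - a) / fps
    }
  }
  if (tsec == 0) return(NA_real_)
  tot / tsec
}

oracle_classify_counts <- function(speed, valid, freeze_thr, rapid_thr) {
  fz <- nm <- rp <- 0L
  for (t in seq_along(speed)) {
    if (!valid[t]) next
    if (speed[t] < freeze_thr) fz <- fz + 1L
    else if (speed[t] > rapid_thr) rp <- rp + 1L
    else nm <- nm + 1L
  }
  c(freezing = fz, normal = nm, rapid = rp)
}

oracle_thigmotaxis <- function(x, y, valid, w, h, band) {
  hits <- 0L; n <- 0L
  for (t in seq_along(x)) {
    if (!valid[t]) next
    n <- n + 1L
    d <- min(x[t], w - x[t], y[t], h - y[t])
    if (d <= band) hits <- hits + 1L
  }
  if (n == 0) return(NA_real_)
  100 * hits / n
}

# maximal true-runs with gap merging and minimum length, by scanning
oracle_bouts <- function(mask, merge_gap, min_bout) {
  mask[is.na(mask)] <- FALSE
  raw <- list()
  t <- 1
  n <- length(mask)
  while (t <= n) {
    if (mask[t]) {
      s <- t
      while (t <= n && mask[t]) t <- t + 1
      raw[[length(raw) + 1]] <- c(s, t - 1)
    } else t <- t + 1
  }
  merged <- list()
  for (b in raw) {
    if (length(merged) &&
        b[1] - merged[[length(merged)]][2] - 1 <= merge_gap)
      merged[[length(merged)]][2] <- b[2]
    else merged[[length(merged) + 1]] <- b
  }
  keep <- Filter(function(b) b[2] - b[1] + 1 >= min_bout, merged)
  if (!length(keep))
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(vapply(keep, `[`, numeric(1), 1)),
             end = as.integer(vapply(keep, `[`, numeric(1), 2)))
}

oracle_threshold_stats <- function(d, valid, thr, below, fps) {
  nv <- sum(valid)
  if (nv == 0) return(list(pct = NA_real_, longest_s = NA_real_))
  hit <- logical(length(d))
  for (t in seq_along(d)) {
    if (!valid[t]) next
    hit[t] <- if (below) d[t] < thr else d[t] > thr
  }
  b <- oracle_bouts(hit, 0, 1)
  longest <- if (nrow(b)) max(b$end - b$start + 1) / fps else 0
  list(pct = 100 * sum(hit) / nv, longest_s = longest)
}

# per-frame minimum distance over a set of cross-individual part pairs
oracle_min_pair <- function(pose, i, j, parts_i, parts_j) {
  n <- pose$n_frames
  d <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (t in seq_len(n)) {
    best <- Inf
    for (pi in parts_i) for (pj in parts_j) {
      if (pose$valid[t, pi, i] && pose$valid[t, pj, j]) {
        dd <- sqrt((pose$x_cm[t, pi, i] - pose$x_cm[t, pj, j])^2 +
                     (pose$y_cm[t, pi, i] - pose$y_cm[t, pj, j])^2)
        if (dd < best) best <- dd
      }
    }
    if (is.finite(best)) { d[t] <- best; valid[t] <- TRUE }
  }
  list(d = d, valid = valid)
}

# per-run linear gap fill, scanning runs explicitly
oracle_fill <- function(v, max_gap) {
  n <- length(v)
  out <- v
  t <- 1
  while (t <= n) {
    if (is.na(v[t])) {
      s <- t
      while (t <= n && is.na(v[t])) t <- t + 1
      e <- t - 1
      if (s > 1 && e < n && e - s + 1 <= max_gap) {
        for (k in s:e)
          out[k] <- v[s - 1] + (v[e + 1] - v[s - 1]) * (k - s + 1) / (e - s + 2)
      }
    } else t <- t + 1
  }
  out
}

# naive UPGMA agglomeration on a distance matrix; returns merge heights
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < bd) { bd <- dd; best <- c(a, b) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# --- fixture builders -------------------------------------------------

# a trial_pose with fully specified coordinate/validity arrays, built
# without the package reader or conditioning path
make_trial_pose <- function(x_cm, y_cm, valid,
                            meta = trial_meta(fps = 25)) {
  structure(list(meta = meta, individuals = dimnames(x_cm)[[3]],
                 bodyparts = dimnames(x_cm)[[2]],
                 n_frames = dim(x_cm)[1],
                 x_cm = x_cm, y_cm = y_cm, valid = valid,
                 n_valid = apply(valid, c(2, 3), sum)),
            class = "trial_pose")
}

random_trial_pose <- function(n_frames, p_valid = 0.9,
                              meta = trial_meta(fps = 25)) {
  dims <- c(n_frames, 5, 2)
  dn <- list(NULL, BODY_PARTS, c("ind1", "ind2"))
  x <- array(runif(prod(dims), 0, meta$arena_w_cm), dims, dimnames = dn)
  y <- array(runif(prod(dims), 0, meta$arena_h_cm), dims, dimnames = dn)
  valid <- array(runif(prod(dims)) < p_valid, dims, dimnames = dn)
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  make_trial_pose(x, y, valid, meta)
}

# a raw_pose built directly from arrays
make_raw_pose <- function(x, y, lik, individuals = c("ind1", "ind2")) {
  dn <- list(NULL, BODY_PARTS, individuals)
  dimnames(x) <- dn; dimnames(y) <- dn; dimnames(lik) <- dn
  structure(list(individuals = individuals, bodyparts = BODY_PARTS,
                 n_frames = dim(x)[1], x = x, y = y, likelihood = lik,
                 scorer = "test", source_path = NA_character_),
            class = "raw_pose")
}

random_raw_pose <- function(n_frames, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c(n_frames, 5, 2)
  x <- array(runif(prod(dims), 0, 1024), dims)
  y <- array(runif(prod(dims), 0, 768), dims)
  lik <- array(runif(prod(dims)), dims)
  make_raw_pose(x, y, lik)
}

# minimal pose CSV text, 2 individuals x 5 parts
write_pose_fixture <- function(path, frames = 3, blank_cell = NULL,
                               shuffle_cols = FALSE) {
  cols <- expand.grid(coord = c("x", "y", "likelihood"),
                      bp = BODY_PARTS, ind = c("ind1", "ind2"),
                      stringsAsFactors = FALSE)
  if (shuffle_cols) cols <- cols[sample(nrow(cols)), ]
  vals <- matrix(round(runif(frames * nrow(cols)), 3), frames)
  vals[, which(cols$coord == "likelihood")] <-
    round(runif(frames * sum(cols$coord == "likelihood"), 0.6, 1), 3)
  ch <- matrix(as.character(vals), frames)
  if (!is.null(blank_cell)) ch[blank_cell[1], blank_cell[2]] <- ""
  lines <- c(paste(c("scorer", rep("test", nrow(cols))), collapse = ","),
             paste(c("individuals", cols$ind), collapse = ","),
             paste(c("bodyparts", cols$bp), collapse = ","),
             paste(c("coords", cols$coord), collapse = ","),
             paste(0:(frames - 1), apply(ch, 1, paste, collapse = ","),
                   sep = ","))
  writeLines(lines, path)
  path
}
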