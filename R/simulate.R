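# Rigid-skeleton geometry of the simulated beetle, in cm relative to
# the scutellum (body centre) along the heading axis. Chosen so the
# behavioural-state geometry keeps the proximity predicates mutually
# exclusive: fighting brings cross mandibles ~0.4 cm apart while
# labrum-to-abdomen stays > 3 cm, chasing holds labrum-to-abdomen at
# 1.5 cm while cross mandibles stay > 3 cm, and the apart-state zones
# keep every cross pair > 3 cm.
SKEL <- list(labrum_fwd = 1.2, abdomen_back = 1.3, mandible_fwd = 0.3)
CHASE_R <- 2.3        # chase circle radius, cm
CHASE_GAP <- 1.5      # chaser labrum to chased abdomen, cm
FIGHT_GAP <- 1.0      # labrum-to-labrum gap in a fight, cm

#' Per-species behavioural parameters for the simulator
#'
#' Dwell-time distributions (mean, sd in seconds) for the solo states
#' (roam, freeze, display) and the joint states (chase, fight),
#' nominal state speeds, mandible gape in and out of display, and an
#' engagement rate controlling how readily the species initiates
#' chases and fights. The defaults describe a moderately active,
#' mildly aggressive beetle in a 10-minute dyadic trial.
#'
#' @param roam_dwell_s,freeze_dwell_s,display_dwell_s length-2
#'   (mean, sd) dwell parameters in seconds.
#' @param solo_probs probabilities of choosing each solo state.
#' @param speed_roam_cm_s,speed_display_cm_s,speed_chase_cm_s nominal
#'   state speeds (freezing and fighting are stationary).
#' @param gape_closed_cm,gape_display_cm mandible gape outside and
#'   inside display bouts; the display value exceeds the 0.5 cm
#'   extension threshold, the closed value does not.
#' @param engage_rate relative propensity to initiate chase/fight
#'   engagements (also sets who tends to be the chaser).
#' @param chase_dwell_s,fight_dwell_s (mean, sd) of joint-state bouts.
#' @return List of class `species_params`.
#' @export
species_params <- function(roam_dwell_s = c(8, 3),
                           freeze_dwell_s = c(6, 2),
                           display_dwell_s = c(4, 2),
                           solo_probs = c(roam = 0.5, freeze = 0.3,
                                          display = 0.2),
                           speed_roam_cm_s = 1.2,
                           speed_display_cm_s = 0.8,
                           speed_chase_cm_s = 3.0,
                           gape_closed_cm = 0.3,
                           gape_display_cm = 0.8,
                           engage_rate = 0.5,
                           chase_dwell_s = c(8, 3),
                           fight_dwell_s = c(6, 3)) {
  stopifnot(all(c(roam_dwell_s[1], freeze_dwell_s[1],
                  display_dwell_s[1], chase_dwell_s[1],
                  fight_dwell_s[1]) > 0),
            abs(sum(solo_probs) - 1) < 1e-9, engage_rate > 0)
  structure(as.list(environment()), class = "species_params")
}

#' Preset phenotypes for cohort simulations
#'
#' `aggressive_params()` plants long, frequent chase and fight bouts
#' and displays; `passive_params()` plants rare, short engagements and
#' long freezing. Used to build cohorts with a known behavioural
#' asymmetry.
#' @return A `species_params` object.
#' @export
aggressive_params <- function() {
  species_params(chase_dwell_s = c(15, 4), fight_dwell_s = c(12, 4),
                 display_dwell_s = c(8, 2),
                 solo_probs = c(roam = 0.45, freeze = 0.1, display = 0.45),
                 engage_rate = 1.5)
}

#' @rdname aggressive_params
#' @export
passive_params <- function() {
  species_params(chase_dwell_s = c(3, 1), fight_dwell_s = c(2, 1),
                 display_dwell_s = c(2, 1),
                 solo_probs = c(roam = 0.35, freeze = 0.6, display = 0.05),
                 engage_rate = 0.15)
}

#' Simulation configuration for one dyadic trial
#'
#' Defines the trial the simulator emulates: a 13 x 8 cm arena imaged
#' at 1024 x 768 px, 600 s at 25 fps, two individuals with
#' per-species behavioural parameters, keypoint jitter and likelihood
#' dropouts below the conditioning cutoff. Explicit schedules may
#' replace the random semi-Markov state machines to plant exact bout
#' structure.
#'
#' @param seed RNG seed; the trial is deterministic given the seed.
#' @param fps frames per second.
#' @param duration_s trial length in seconds.
#' @param arena_w_cm,arena_h_cm,width_px,height_px,px_per_cm arena
#'   and imaging geometry, see [trial_meta()].
#' @param jitter_sd_cm isotropic keypoint jitter sd in cm.
#' @param dropout_rate probability a keypoint sample is assigned a
#'   likelihood below `pcutoff` (and so is discarded downstream).
#' @param pcutoff conditioning cutoff the dropout model straddles:
#'   retained samples draw likelihood uniformly from
#'   `[pcutoff, 1]`, dropped samples from `[0, pcutoff)`.
#' @param species_a,species_b species labels of individuals 1 and 2.
#' @param params_a,params_b [species_params()] for each individual.
#' @param pair_schedule optional data frame (`state`, `start_s`,
#'   `end_s`, optional `chaser`) planting the joint timeline; states
#'   `apart`, `chase`, `fight`; uncovered time is apart.
#' @param ind_schedule optional list of two data frames (`state`,
#'   `start_s`, `end_s`) planting the solo timelines (applied on
#'   apart frames; states `roam`, `freeze`, `display`).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, fps = 25, duration_s = 600,
                       arena_w_cm = 13, arena_h_cm = 8,
                       width_px = 1024L, height_px = 768L,
                       px_per_cm = width_px / arena_w_cm,
                       jitter_sd_cm = 0.02, dropout_rate = 0.02,
                       pcutoff = 0.6,
                       species_a = "A", species_b = "B",
                       params_a = species_params(),
                       params_b = species_params(),
                       pair_schedule = NULL, ind_schedule = NULL) {
  stopifnot(fps > 0, duration_s > 0, jitter_sd_cm >= 0,
            dropout_rate >= 0, dropout_rate < 1,
            pcutoff >= 0, pcutoff <= 1)
  structure(as.list(environment()), class = "sim_config")
}

draw_dwell <- function(ms, fps) {
  max(1L, as.integer(round(stats::rnorm(1, ms[1], ms[2]) * fps)))
}

# expand a (state, start_s, end_s) schedule into a per-frame vector;
# overlapping rows are an integrity error, uncovered frames get `fill`
schedule_to_frames <- function(sched, n, fps, fill, allowed) {
  out <- rep(fill, n)
  claimed <- rep(FALSE, n)
  ch <- rep(NA_integer_, n)
  for (r in seq_len(nrow(sched))) {
    st <- as.character(sched$state[r])
    if (!st %in% allowed)
      stop("schedule state '", st, "' not one of: ",
           paste(allowed, collapse = ", "))
    a <- as.integer(round(sched$start_s[r] * fps)) + 1L
    b <- as.integer(round(sched$end_s[r] * fps))
    if (a < 1 || b > n || b < a)
      stop("schedule interval [", sched$start_s[r], ", ",
           sched$end_s[r], "] s outside the trial")
    if (any(claimed[a:b]))
      stop("overlapping states in schedule (integrity error)")
    claimed[a:b] <- TRUE
    out[a:b] <- st
    if (!is.null(sched$chaser)) ch[a:b] <- as.integer(sched$chaser[r])
  }
  list(state = out, chaser = ch)
}

# random joint timeline over apart / chase / fight
sample_pair_frames <- function(cfg, n) {
  pa <- cfg$params_a; pb <- cfg$params_b
  apart_mean <- 30 / (pa$engage_rate + pb$engage_rate)
  apart_ms <- c(apart_mean, 0.3 * apart_mean)
  chase_ms <- (pa$chase_dwell_s + pb$chase_dwell_s) / 2
  fight_ms <- (pa$fight_dwell_s + pb$fight_dwell_s) / 2
  chaser_prob_a <- pa$engage_rate / (pa$engage_rate + pb$engage_rate)
  state <- character(0); chaser <- integer(0)
  cur <- "apart"; tot <- 0L
  while (tot < n) {
    dw <- switch(cur,
                 apart = draw_dwell(apart_ms, cfg$fps),
                 chase = draw_dwell(chase_ms, cfg$fps),
                 fight = draw_dwell(fight_ms, cfg$fps))
    dw <- min(dw, n - tot)
    state <- c(state, rep(cur, dw))
    chaser <- c(chaser, rep(if (cur == "chase")
      ifelse(stats::runif(1) < chaser_prob_a, 1L, 2L)
      else NA_integer_, dw))
    tot <- tot + dw
    cur <- switch(cur,
                  apart = ifelse(stats::runif(1) < 0.5, "chase", "fight"),
                  chase = ifelse(stats::runif(1) < 0.7, "apart", "fight"),
                  fight = ifelse(stats::runif(1) < 0.8, "apart", "chase"))
  }
  list(state = state, chaser = chaser)
}

# random solo timeline per individual, resampled inside each apart run
sample_solo_frames <- function(params, seg_len, fps) {
  out <- character(0)
  while (length(out) < seg_len) {
    st <- sample(names(params$solo_probs), 1, prob = params$solo_probs)
    dw <- draw_dwell(params[[paste0(st, "_dwell_s")]], fps)
    out <- c(out, rep(st, min(dw, seg_len - length(out))))
  }
  out
}

state_speed <- function(state, params) {
  switch(state,
         roam = params$speed_roam_cm_s,
         display = params$speed_display_cm_s,
         chase = params$speed_chase_cm_s,
         chased = params$speed_chase_cm_s,
         freeze = 0, fight = 0,
         stop("unknown state: ", state))
}

# angular offset of the chaser behind the chased on the chase circle
# such that the chaser's labrum sits exactly CHASE_GAP from the
# chased individual's abdomen
chase_delta <- function() {
  f <- function(delta) {
    th <- 0
    ph <- th - delta
    chased_ab <- c(CHASE_R * cos(th), CHASE_R * sin(th)) -
      SKEL$abdomen_back * c(-sin(th), cos(th))
    chaser_la <- c(CHASE_R * cos(ph), CHASE_R * sin(ph)) +
      SKEL$labrum_fwd * c(-sin(ph), cos(ph))
    sqrt(sum((chased_ab - chaser_la)^2)) - CHASE_GAP
  }
  # the root with the chaser fully behind the chased lies beyond the
  # arc at which the two bodies would overlap
  lower <- (SKEL$labrum_fwd + SKEL$abdomen_back) / CHASE_R
  stats::uniroot(f, c(lower, pi))$root
}

#' Simulate one dyadic trial
#'
#' Runs the semi-Markov behavioural state machine (chase and fight
#' are joint states coupling both individuals), renders each
#' individual as a rigid five-point skeleton, integrates positions
#' with reflective walls inside per-individual home zones, scales to
#' pixels, adds keypoint jitter and likelihood dropouts, and returns
#' both the raw pose dataset and the ground-truth state log.
#'
#' @param cfg a [sim_config()].
#' @return List: `pose` (a `raw_pose`), `truth` (a `truth_log`
#'   holding the per-frame joint state, chaser identity and solo
#'   states), `meta` (the matching [trial_meta()]).
#' @examples
#' sim <- simulate_trial(sim_config(duration_s = 10, seed = 42))
#' sim$pose
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  n <- as.integer(round(cfg$duration_s * cfg$fps))
  fps <- cfg$fps
  params <- list(cfg$params_a, cfg$params_b)

  # joint timeline
  if (!is.null(cfg$pair_schedule)) {
    pf <- schedule_to_frames(cfg$pair_schedule, n, fps, "apart",
                             c("apart", "chase", "fight"))
    if (any(pf$state == "chase" & is.na(pf$chaser)))
      stop("pair_schedule chase rows need a 'chaser' column (1 or 2)")
  } else {
    pf <- sample_pair_frames(cfg, n)
  }
  ps <- pf$state[seq_len(n)]
  ch <- pf$chaser[seq_len(n)]

  # solo timelines on apart frames
  st <- matrix("", n, 2)
  st[ps == "fight", ] <- "fight"
  for (i in 1:2) {
    st[ps == "chase", i] <- ifelse(ch[ps == "chase"] == i,
                                   "chase", "chased")
  }
  apart_runs <- rle(ps == "apart")
  ends <- cumsum(apart_runs$lengths)
  starts <- ends - apart_runs$lengths + 1L
  for (i in 1:2) {
    if (!is.null(cfg$ind_schedule)) {
      sf <- schedule_to_frames(cfg$ind_schedule[[i]], n, fps, "roam",
                               c("roam", "freeze", "display"))$state
      st[ps == "apart", i] <- sf[ps == "apart"]
    } else {
      for (k in which(apart_runs$values)) {
        seg <- starts[k]:ends[k]
        st[seg, i] <- sample_solo_frames(params[[i]], length(seg), fps)
      }
    }
  }

  # home zones keeping every cross-individual pair > 3 cm when apart
  w <- cfg$arena_w_cm; h <- cfg$arena_h_cm
  zones <- list(c(1.7, 3.4, 1.8, h - 1.8),
                c(w - 3.4, w - 1.7, 1.8, h - 1.8))
  centre <- c(w / 2, h / 2)
  delta <- chase_delta()
  omega <- params[[1]]$speed_chase_cm_s / CHASE_R / fps

  sx <- matrix(NA_real_, n, 2); sy <- matrix(NA_real_, n, 2)
  hd <- matrix(NA_real_, n, 2)
  pos <- rbind(c(mean(zones[[1]][1:2]), mean(zones[[1]][3:4])),
               c(mean(zones[[2]][1:2]), mean(zones[[2]][3:4])))
  head_ang <- stats::runif(2, 0, 2 * pi)
  theta <- NA_real_

  for (t in seq_len(n)) {
    if (ps[t] == "apart") {
      if (t > 1 && ps[t - 1] != "apart") {
        pos <- rbind(c(mean(zones[[1]][1:2]), mean(zones[[1]][3:4])),
                     c(mean(zones[[2]][1:2]), mean(zones[[2]][3:4])))
        head_ang <- stats::runif(2, 0, 2 * pi)
      }
      for (i in 1:2) {
        sp <- state_speed(st[t, i], params[[i]])
        if (sp > 0) {
          head_ang[i] <- head_ang[i] + stats::rnorm(1, 0, 0.25)
          step <- sp / fps
          px <- pos[i, 1] + step * cos(head_ang[i])
          py <- pos[i, 2] + step * sin(head_ang[i])
          z <- zones[[i]]
          if (px < z[1]) { px <- 2 * z[1] - px; head_ang[i] <- pi - head_ang[i] }
          if (px > z[2]) { px <- 2 * z[2] - px; head_ang[i] <- pi - head_ang[i] }
          if (py < z[3]) { py <- 2 * z[3] - py; head_ang[i] <- -head_ang[i] }
          if (py > z[4]) { py <- 2 * z[4] - py; head_ang[i] <- -head_ang[i] }
          pos[i, ] <- c(px, py)
        }
      }
      sx[t, ] <- pos[, 1]; sy[t, ] <- pos[, 2]; hd[t, ] <- head_ang
    } else if (ps[t] == "chase") {
      new_bout <- t == 1 || ps[t - 1] != "chase" ||
        (!is.na(ch[t - 1]) && ch[t - 1] != ch[t])
      theta <- if (new_bout) stats::runif(1, 0, 2 * pi) else theta + omega
      ci <- ch[t]; oi <- 3L - ci
      sx[t, oi] <- centre[1] + CHASE_R * cos(theta)
      sy[t, oi] <- centre[2] + CHASE_R * sin(theta)
      hd[t, oi] <- theta + pi / 2
      phi <- theta - delta
      sx[t, ci] <- centre[1] + CHASE_R * cos(phi)
      sy[t, ci] <- centre[2] + CHASE_R * sin(phi)
      hd[t, ci] <- phi + pi / 2
    } else {                               # fight: head-to-head, static
      off <- SKEL$labrum_fwd + FIGHT_GAP / 2
      sx[t, 1] <- centre[1] - off; sy[t, 1] <- centre[2]; hd[t, 1] <- 0
      sx[t, 2] <- centre[1] + off; sy[t, 2] <- centre[2]; hd[t, 2] <- pi
    }
  }

  # render the rigid skeleton
  gape <- matrix(params[[1]]$gape_closed_cm, n, 2)
  for (i in 1:2) {
    gape[, i] <- ifelse(st[, i] == "display",
                        params[[i]]$gape_display_cm,
                        params[[i]]$gape_closed_cm)
  }
  dims <- c(n, length(BODY_PARTS), 2L)
  dn <- list(NULL, BODY_PARTS, c("ind1", "ind2"))
  x <- array(NA_real_, dims, dimnames = dn)
  y <- array(NA_real_, dims, dimnames = dn)
  for (i in 1:2) {
    ux <- cos(hd[, i]); uy <- sin(hd[, i])
    nx <- -sin(hd[, i]); ny <- cos(hd[, i])
    lx <- sx[, i] + SKEL$labrum_fwd * ux
    ly <- sy[, i] + SKEL$labrum_fwd * uy
    x[, "labrum", i] <- lx; y[, "labrum", i] <- ly
    x[, "scutellum", i] <- sx[, i]; y[, "scutellum", i] <- sy[, i]
    x[, "abdomen", i] <- sx[, i] - SKEL$abdomen_back * ux
    y[, "abdomen", i] <- sy[, i] - SKEL$abdomen_back * uy
    mx <- lx + SKEL$mandible_fwd * ux
    my <- ly + SKEL$mandible_fwd * uy
    x[, "left_mandible", i] <- mx + gape[, i] / 2 * nx
    y[, "left_mandible", i] <- my + gape[, i] / 2 * ny
    x[, "right_mandible", i] <- mx - gape[, i] / 2 * nx
    y[, "right_mandible", i] <- my - gape[, i] / 2 * ny
  }
  if (cfg$jitter_sd_cm > 0) {
    x <- x + stats::rnorm(length(x), 0, cfg$jitter_sd_cm)
    y <- y + stats::rnorm(length(y), 0, cfg$jitter_sd_cm)
  }
  x <- pmin(pmax(x * cfg$px_per_cm, 0), cfg$width_px)
  y <- pmin(pmax(y * cfg$px_per_cm, 0), cfg$height_px)

  drop <- array(stats::runif(length(x)) < cfg$dropout_rate, dims)
  lik <- array(stats::runif(length(x), cfg$pcutoff, 1), dims,
               dimnames = dn)
  if (any(drop))
    lik[drop] <- stats::runif(sum(drop), 0, cfg$pcutoff * 0.999)

  pose <- structure(list(individuals = c("ind1", "ind2"),
                         bodyparts = BODY_PARTS, n_frames = n,
                         x = x, y = y, likelihood = lik,
                         scorer = "stagpose-sim",
                         source_path = NA_character_),
                    class = "raw_pose")
  truth <- structure(list(pair_state = ps, chaser = ch,
                          ind_states = st, n_frames = n, cfg = cfg),
                     class = "truth_log")
  meta <- trial_meta(species_a = cfg$species_a,
                     species_b = cfg$species_b,
                     arena_w_cm = cfg$arena_w_cm,
                     arena_h_cm = cfg$arena_h_cm,
                     width_px = cfg$width_px, height_px = cfg$height_px,
                     px_per_cm = cfg$px_per_cm, fps = fps,
                     duration_s = cfg$duration_s)
  list(pose = pose, truth = truth, meta = meta)
}

longest_run_s <- function(mask, fps) {
  r <- rle(mask)
  if (!any(r$values)) return(0)
  max(r$lengths[r$values]) / fps
}

#' Closed-form truth endpoints from a simulator state log
#'
#' Computes what every behavioural endpoint should be, directly from
#' the planted state timeline: extension equals the display time
#' share, contact the fight share, directional chasing the share of
#' frames the individual is the chaser, interaction the joint
#' chase-or-fight share; longest bouts come from timeline run
#' lengths. Movement classes follow each state's nominal speed
#' (freeze and fight are stationary, hence truth-freezing), and
#' total distance is the nominal-speed integral — exact up to the
#' single-frame transitions between states.
#'
#' @param truth a `truth_log` from [simulate_trial()].
#' @param config a [stagpose_config()] providing the speed-class
#'   thresholds.
#' @param trial_id label for the output records.
#' @return Endpoint records in the same long format as
#'   [trial_endpoints()].
#' @export
truth_endpoints <- function(truth, config = stagpose_config(),
                            trial_id = "sim") {
  stopifnot(inherits(truth, "truth_log"))
  cfg <- truth$cfg
  n <- truth$n_frames
  fps <- cfg$fps
  ps <- truth$pair_state
  species <- c(cfg$species_a, cfg$species_b)
  pairing <- if (cfg$species_a == cfg$species_b) "intra" else "inter"
  params <- list(cfg$params_a, cfg$params_b)
  inter_mask <- ps %in% c("chase", "fight")
  rows <- list()
  for (i in 1:2) {
    s <- truth$ind_states[, i]
    speeds <- vapply(s, state_speed, numeric(1), params = params[[i]])
    chase_mask <- ps == "chase" & !is.na(truth$chaser) & truth$chaser == i
    vals <- c(
      extended_mandible_pct = 100 * mean(s == "display"),
      total_distance_cm = sum(speeds) / fps,
      avg_speed_cm_s = sum(speeds) / fps / (n / fps),
      freezing_s = sum(speeds < config$freeze_thr_cm_s) / fps,
      normal_s = sum(speeds >= config$freeze_thr_cm_s &
                       speeds <= config$rapid_thr_cm_s) / fps,
      rapid_s = sum(speeds > config$rapid_thr_cm_s) / fps,
      thigmotaxis_pct = 0,
      interaction_pct = 100 * mean(inter_mask),
      longest_interaction_s = longest_run_s(inter_mask, fps),
      chasing_pct = 100 * mean(chase_mask),
      longest_chasing_s = longest_run_s(chase_mask, fps),
      contact_pct = 100 * mean(ps == "fight"),
      longest_contact_s = longest_run_s(ps == "fight", fps))
    rows[[i]] <- data.frame(
      trial_id = trial_id, pairing = pairing, species = species[i],
      individual = paste0("ind", i), endpoint = names(vals),
      value = unname(vals),
      units = unname(ENDPOINT_UNITS[names(vals)]),
      denominator_s = n / fps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of dyadic trials
#'
#' Emulates a study design of intra- and inter-species pairings:
#' every species against itself and (optionally) every unordered
#' inter-species combination, `n_trials` trials each. Per-trial seeds
#' are derived deterministically from `seed`. With `out_dir` set,
#' each trial's pose data is written as a multi-animal pose CSV and
#' the planted truth endpoints as one cohort CSV.
#'
#' @param species named list of [species_params()], one per species.
#' @param n_trials trials per pairing.
#' @param seed cohort seed.
#' @param pairs optional data frame (`species_a`, `species_b`)
#'   selecting pairings; default all intra + inter combinations.
#' @param out_dir optional output directory.
#' @param ... further arguments passed to [sim_config()] (fps,
#'   duration_s, jitter_sd_cm, dropout_rate, ...).
#' @return List: `trials` (list of [simulate_trial()] results, named
#'   `<paircode>_<k>`), `truth` (combined truth endpoint records),
#'   `files` (paths written, or NULL).
#' @export
simulate_cohort <- function(species, n_trials = 7, seed = 1L,
                            pairs = NULL, out_dir = NULL, ...) {
  stopifnot(n_trials >= 1, length(species) >= 1,
            !is.null(names(species)))
  nm <- names(species)
  if (is.null(pairs)) {
    intra <- data.frame(species_a = nm, species_b = nm)
    inter <- if (length(nm) > 1) {
      cmb <- utils::combn(nm, 2)
      data.frame(species_a = cmb[1, ], species_b = cmb[2, ])
    } else NULL
    pairs <- rbind(intra, inter)
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L,
                            nrow(pairs) * n_trials)
  trials <- list()
  truth_tabs <- list()
  files <- character(0)
  k <- 0L
  for (p in seq_len(nrow(pairs))) {
    sa <- pairs$species_a[p]; sb <- pairs$species_b[p]
    code <- paste0(sa, sb)
    for (tr in seq_len(n_trials)) {
      k <- k + 1L
      tid <- sprintf("%s_%02d", code, tr)
      cfg <- sim_config(seed = trial_seeds[k],
                        species_a = sa, species_b = sb,
                        params_a = species[[sa]],
                        params_b = species[[sb]], ...)
      sim <- simulate_trial(cfg)
      trials[[tid]] <- sim
      truth_tabs[[tid]] <- truth_endpoints(sim$truth, trial_id = tid)
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir))
          dir.create(out_dir, recursive = TRUE)
        f <- file.path(out_dir, paste0(tid, ".csv"))
        write_pose_csv(sim$pose, f)
        files <- c(files, f)
      }
    }
  }
  truth <- do.call(rbind, truth_tabs)
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    tf <- file.path(out_dir, "cohort_truth.csv")
    utils::write.csv(truth, tf, row.names = FALSE)
    files <- c(files, tf)
  }
  list(trials = trials, truth = truth,
       files = if (length(files)) files else NULL)
}
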