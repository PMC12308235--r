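#' Compute the thirteen behavioural endpoints for one trial
#'
#' Runs the full per-trial endpoint battery on a conditioned
#' `trial_pose`: per-individual locomotion (total distance, average
#' speed, freezing/normal/rapid partition, thigmotaxis), the
#' extended-mandible display, and the dyadic proximity endpoints
#' (interaction, chasing, mandible contact). Chasing is reported per
#' individual in its own direction (the individual as chaser);
#' contact and interaction are pair-symmetric and identical for both
#' individuals. Every ratio's denominator (valid observation time of
#' its own series) is reported alongside.
#'
#' @param pose a `trial_pose` from [condition_pose()].
#' @param config a [stagpose_config()].
#' @param trial_id trial label.
#' @return Long-format data frame: `trial_id`, `pairing`, `species`,
#'   `individual`, `endpoint`, `value`, `units`, `denominator_s`.
#' @examples
#' sim <- simulate_trial(sim_config(duration_s = 20, seed = 7))
#' tp <- condition_pose(sim$pose, sim$meta)
#' head(trial_endpoints(tp, trial_id = "demo"))
#' @export
trial_endpoints <- function(pose, config = stagpose_config(),
                            trial_id = "trial") {
  stopifnot(inherits(pose, "trial_pose"))
  meta <- pose$meta
  fps <- meta$fps
  species <- c(meta$species_a, meta$species_b)
  pairing <- if (meta$species_a == meta$species_b) "intra" else "inter"
  inds <- pose$individuals

  inter_s <- interaction_series(pose, inds[1], inds[2])
  inter_ep <- interaction_endpoints(inter_s, config$interaction_thr_cm,
                                    config$merge_gap_frames,
                                    config$min_bout_frames)
  cont_s <- mandible_contact_series(pose, inds[1], inds[2])
  cont_ep <- contact_endpoints(cont_s, config$contact_thr_cm,
                               config$merge_gap_frames,
                               config$min_bout_frames)

  rows <- list()
  for (i in 1:2) {
    ind <- inds[i]
    other <- inds[3 - i]
    ref <- reference_point(pose, ind, config$reference_part)
    dist_cm <- total_distance(ref, config$max_gap_frames)
    spd <- average_speed(ref, fps, config$max_gap_frames)
    ss <- speed_series(ref, fps)
    mv <- classify_movement(ss, config$freeze_thr_cm_s,
                            config$rapid_thr_cm_s)
    thig <- thigmotaxis_ratio(ref, meta, config$band_cm)
    g <- mandible_gape(pose, ind)
    ext <- extended_mandible_ratio(g, config$gape_thr_cm,
                                   config$merge_gap_frames,
                                   config$min_bout_frames)
    chs <- chase_series(pose, chaser = ind, chased = other)
    ch_ep <- chasing_endpoints(chs, config$chase_thr_cm,
                               merge_gap_frames = config$merge_gap_frames,
                               min_bout_frames = config$min_bout_frames)
    ref_valid_s <- sum(ref$valid) / fps

    vals <- c(extended_mandible_pct = ext$pct,
              total_distance_cm = dist_cm,
              avg_speed_cm_s = spd,
              freezing_s = mv$freezing_s,
              normal_s = mv$normal_s,
              rapid_s = mv$rapid_s,
              thigmotaxis_pct = thig,
              interaction_pct = inter_ep$pct,
              longest_interaction_s = inter_ep$longest_s,
              chasing_pct = ch_ep$pct,
              longest_chasing_s = ch_ep$longest_s,
              contact_pct = cont_ep$pct,
              longest_contact_s = cont_ep$longest_s)
    denom <- c(extended_mandible_pct = ext$valid_s,
               total_distance_cm = ref_valid_s,
               avg_speed_cm_s = ref_valid_s,
               freezing_s = mv$valid_s,
               normal_s = mv$valid_s,
               rapid_s = mv$valid_s,
               thigmotaxis_pct = ref_valid_s,
               interaction_pct = inter_ep$valid_s,
               longest_interaction_s = inter_ep$valid_s,
               chasing_pct = ch_ep$valid_s,
               longest_chasing_s = ch_ep$valid_s,
               contact_pct = cont_ep$valid_s,
               longest_contact_s = cont_ep$valid_s)
    rows[[i]] <- data.frame(
      trial_id = trial_id, pairing = pairing, species = species[i],
      individual = ind, endpoint = names(vals), value = unname(vals),
      units = unname(ENDPOINT_UNITS[names(vals)]),
      denominator_s = unname(denom))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-trial bout table
#'
#' Extracts the bouts behind every thresholded dyadic endpoint of one
#' trial: extension per individual, directional chasing, mandible
#' contact and interaction for the pair.
#'
#' @inheritParams trial_endpoints
#' @return Data frame: `trial_id`, `endpoint`, `direction`,
#'   `start_s`, `end_s`, `duration_s`.
#' @export
trial_bouts <- function(pose, config = stagpose_config(),
                        trial_id = "trial") {
  stopifnot(inherits(pose, "trial_pose"))
  fps <- pose$meta$fps
  inds <- pose$individuals
  pieces <- list()
  add <- function(ep_res, endpoint, direction) {
    b <- ep_res$bouts$bouts
    if (is.null(b) || !nrow(b)) return()
    pieces[[length(pieces) + 1L]] <<- data.frame(
      trial_id = trial_id, endpoint = endpoint, direction = direction,
      start_s = (b$start_frame - 1L) / fps,
      end_s = b$end_frame / fps,
      duration_s = b$n_frames / fps)
  }
  for (ind in inds) {
    g <- mandible_gape(pose, ind)
    add(extended_mandible_ratio(g, config$gape_thr_cm,
                                config$merge_gap_frames,
                                config$min_bout_frames),
        "extended_mandible", ind)
    other <- setdiff(inds, ind)
    chs <- chase_series(pose, ind, other)
    add(chasing_endpoints(chs, config$chase_thr_cm,
                          merge_gap_frames = config$merge_gap_frames,
                          min_bout_frames = config$min_bout_frames),
        "chasing", paste0(ind, "->", other))
  }
  add(contact_endpoints(mandible_contact_series(pose, inds[1], inds[2]),
                        config$contact_thr_cm, config$merge_gap_frames,
                        config$min_bout_frames),
      "contact", "pair")
  add(interaction_endpoints(interaction_series(pose, inds[1], inds[2]),
                            config$interaction_thr_cm,
                            config$merge_gap_frames,
                            config$min_bout_frames),
      "interaction", "pair")
  if (!length(pieces))
    return(data.frame(trial_id = character(0), endpoint = character(0),
                      direction = character(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0)))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
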