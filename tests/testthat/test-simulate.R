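test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_trial(sim_config(duration_s = 8, seed = 99))
  b <- simulate_trial(sim_config(duration_s = 8, seed = 99))
  expect_identical(a$pose$x, b$pose$x)
  expect_identical(a$pose$likelihood, b$pose$likelihood)
  expect_identical(a$truth$pair_state, b$truth$pair_state)
  c2 <- simulate_trial(sim_config(duration_s = 8, seed = 100))
  expect_false(identical(a$pose$x, c2$pose$x))
})

test_that("generated coordinates stay inside the image frame", {
  sim <- simulate_trial(sim_config(duration_s = 30, seed = 13,
                                   jitter_sd_cm = 0.1))
  expect_true(all(sim$pose$x >= 0 & sim$pose$x <= 1024))
  expect_true(all(sim$pose$y >= 0 & sim$pose$y <= 768))
  expect_true(all(sim$pose$likelihood >= 0 & sim$pose$likelihood <= 1))
})

test_that("dropout fraction matches its nominal rate", {
  sim <- simulate_trial(sim_config(duration_s = 120, seed = 14,
                                   dropout_rate = 0.3))
  frac <- mean(sim$pose$likelihood < 0.6)
  n <- length(sim$pose$likelihood)
  ci <- 0.3 + c(-4, 4) * sqrt(0.3 * 0.7 / n)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("noise-free simulated trials reproduce truth endpoints", {
  sim <- simulate_trial(sim_config(duration_s = 90, seed = 15,
                                   jitter_sd_cm = 0, dropout_rate = 0))
  tp <- condition_pose(sim$pose, sim$meta)
  ep <- trial_endpoints(tp, trial_id = "t")
  te <- truth_endpoints(sim$truth, trial_id = "t")
  m <- merge(ep, te, by = c("individual", "endpoint"))
  exact <- c("extended_mandible_pct", "chasing_pct", "contact_pct",
             "interaction_pct", "longest_chasing_s",
             "longest_contact_s", "longest_interaction_s",
             "thigmotaxis_pct")
  sub <- m[m$endpoint %in% exact, ]
  expect_equal(sub$value.x, sub$value.y, tolerance = 1e-9)
  # movement classes agree to about one frame per state transition
  for (i in 1:2) {
    runs <- length(rle(sim$truth$ind_states[, i])$lengths)
    for (epn in c("freezing_s", "normal_s", "rapid_s")) {
      sm <- m[m$endpoint == epn & m$individual == paste0("ind", i), ]
      expect_lt(abs(sm$value.x - sm$value.y), (runs + 2) / 25)
    }
  }
})

test_that("truth endpoints follow the planted schedule in closed form", {
  cfg <- sim_config(
    duration_s = 600, seed = 16, jitter_sd_cm = 0, dropout_rate = 0,
    pair_schedule = data.frame(state = "fight", start_s = 100,
                               end_s = 130),
    ind_schedule = list(
      data.frame(state = c("display", "freeze"),
                 start_s = c(0, 60), end_s = c(60, 600)),
      data.frame(state = "freeze", start_s = 0, end_s = 600)))
  sim <- simulate_trial(cfg)
  te <- truth_endpoints(sim$truth)
  v <- function(ind, ep) te$value[te$individual == ind & te$endpoint == ep]
  expect_equal(v("ind1", "extended_mandible_pct"), 10)  # 60 of 600 s
  expect_equal(v("ind1", "contact_pct"), 5)             # 30 of 600 s
  expect_equal(v("ind1", "longest_contact_s"), 30)
  expect_equal(v("ind2", "extended_mandible_pct"), 0)
  # ind2 freezes except the fight; both stationary states are freezing
  expect_equal(v("ind2", "freezing_s"), 600)
  expect_equal(v("ind2", "chasing_pct"), 0)
})

test_that("an all-freeze schedule yields zero everywhere but freezing", {
  cfg <- sim_config(
    duration_s = 600, seed = 17, jitter_sd_cm = 0, dropout_rate = 0,
    pair_schedule = data.frame(state = "apart", start_s = 0, end_s = 600),
    ind_schedule = list(
      data.frame(state = "freeze", start_s = 0, end_s = 600),
      data.frame(state = "freeze", start_s = 0, end_s = 600)))
  te <- truth_endpoints(simulate_trial(cfg)$truth)
  expect_equal(te$value[te$endpoint == "freezing_s"], c(600, 600))
  for (ep in c("extended_mandible_pct", "chasing_pct", "contact_pct",
               "interaction_pct", "total_distance_cm"))
    expect_equal(te$value[te$endpoint == ep], c(0, 0))
})

test_that("overlapping planted states raise an integrity error", {
  cfg <- sim_config(
    duration_s = 10, seed = 18,
    pair_schedule = data.frame(state = c("fight", "chase"),
                               start_s = c(0, 3), end_s = c(5, 8),
                               chaser = c(NA, 1)))
  expect_error(simulate_trial(cfg), "overlapping")
})

test_that("cohorts expand pairings and plant species asymmetries", {
  dir <- withr::local_tempdir()
  sims <- simulate_cohort(
    species = list(A = species_params(), B = species_params(),
                   C = species_params(), D = species_params()),
    pairs = data.frame(species_a = c("A", "B", "C", "D"),
                       species_b = c("A", "B", "C", "D")),
    n_trials = 2, seed = 19, duration_s = 10, out_dir = dir)
  expect_length(sims$trials, 8)            # 4 intra groups x 2 trials
  expect_length(grep("cohort_truth", sims$files, invert = TRUE,
                     value = TRUE), 8)
  expect_true(file.exists(file.path(dir, "cohort_truth.csv")))

  agg <- simulate_cohort(
    species = list(P = passive_params(), Q = aggressive_params()),
    pairs = data.frame(species_a = c("P", "Q")[c(1, 2)],
                       species_b = c("P", "Q")[c(1, 2)]),
    n_trials = 3, seed = 20, duration_s = 60)
  tr <- agg$truth
  mean_chase <- function(sp)
    mean(tr$value[tr$species == sp & tr$endpoint == "chasing_pct"])
  expect_gt(mean_chase("Q"), mean_chase("P"))
})
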