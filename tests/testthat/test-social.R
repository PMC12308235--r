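posed <- function(setter, n = 1) {
  dims <- c(n, 5, 2)
  dn <- list(NULL, BODY_PARTS, c("ind1", "ind2"))
  x <- array(0, dims, dimnames = dn); y <- array(0, dims, dimnames = dn)
  v <- array(TRUE, dims, dimnames = dn)
  env <- list(x = x, y = y, v = v)
  env <- setter(env)
  make_trial_pose(env$x, env$y, env$v)
}

test_that("mandible gape is the left-right mandible distance", {
  tp <- posed(function(e) {
    e$x[1, "left_mandible", "ind1"] <- 0
    e$x[1, "right_mandible", "ind1"] <- 0.6
    e
  })
  g <- mandible_gape(tp, "ind1")
  expect_equal(g$d_cm[1], 0.6)

  tp$valid[1, "left_mandible", "ind1"] <- FALSE
  g2 <- mandible_gape(tp, "ind1")
  expect_false(g2$valid[1])
  expect_true(is.na(g2$d_cm[1]))
})

test_that("gape distances match a hypot oracle on random poses", {
  set.seed(51)
  tp <- random_trial_pose(100)
  g <- mandible_gape(tp, "ind1")
  for (t in seq_len(100)) {
    if (tp$valid[t, "left_mandible", "ind1"] &&
        tp$valid[t, "right_mandible", "ind1"]) {
      expect_equal(g$d_cm[t],
                   sqrt((tp$x_cm[t, 2, 1] - tp$x_cm[t, 3, 1])^2 +
                          (tp$y_cm[t, 2, 1] - tp$y_cm[t, 3, 1])^2),
                   tolerance = 1e-9)
    } else expect_false(g$valid[t])
  }
})

test_that("mandible extension uses a strict exceedance threshold", {
  mk <- function(d) structure(list(d_cm = d, valid = rep(TRUE, length(d)),
                                   definition = "gape", fps = 25),
                              class = "distance_series")
  expect_equal(extended_mandible_ratio(mk(rep(0.6, 10)), 0.5)$pct, 100)
  expect_equal(extended_mandible_ratio(mk(rep(0.5, 10)), 0.5)$pct, 0)
  r <- extended_mandible_ratio(mk(rep(0.4, 15000)), 0.5)
  expect_equal(r$pct, 0)
  expect_equal(r$longest_s, 0)
  none <- mk(rep(1, 5)); none$valid[] <- FALSE; none$d_cm[] <- NA
  expect_true(is.na(extended_mandible_ratio(none, 0.5)$pct))
})

test_that("contact series is the 4-pair cross-mandible minimum", {
  # only right(i)-left(j) valid: min over a singleton
  tp <- posed(function(e) {
    e$x[1, "right_mandible", "ind1"] <- 1
    e$x[1, "left_mandible", "ind2"] <- 3
    e$v[1, "left_mandible", "ind1"] <- FALSE
    e$v[1, "right_mandible", "ind2"] <- FALSE
    e
  })
  s <- mandible_contact_series(tp, "ind1", "ind2")
  expect_equal(s$d_cm[1], 2)

  set.seed(52)
  tp <- random_trial_pose(80)
  s12 <- mandible_contact_series(tp, "ind1", "ind2")
  s21 <- mandible_contact_series(tp, "ind2", "ind1")
  expect_equal(s12$d_cm, s21$d_cm)         # symmetric
  orc <- oracle_min_pair(tp, "ind1", "ind2",
                         c("left_mandible", "right_mandible"),
                         c("left_mandible", "right_mandible"))
  expect_equal(s12$d_cm, orc$d, tolerance = 1e-9)
  expect_equal(s12$valid, orc$valid)
  expect_error(mandible_contact_series(tp, "ind1", "ind1"), "differ")
})

test_that("contact endpoints use a strict below-threshold rule", {
  mk <- function(d, fps = 25) structure(
    list(d_cm = d, valid = rep(TRUE, length(d)), definition = "contact",
         fps = fps), class = "distance_series")
  full <- contact_endpoints(mk(rep(2.9, 15000)), 3)
  expect_equal(full$pct, 100)
  expect_equal(full$longest_s, 600)
  expect_equal(contact_endpoints(mk(rep(3.0, 100)), 3)$pct, 0)
})

test_that("chase series is directional labrum-to-abdomen distance", {
  tp <- posed(function(e) {
    e$x[1, "labrum", "ind1"] <- 1; e$y[1, "labrum", "ind1"] <- 1
    e$x[1, "abdomen", "ind2"] <- 4; e$y[1, "abdomen", "ind2"] <- 5
    e
  })
  expect_equal(chase_series(tp, "ind1", "ind2")$d_cm[1], 5)  # 3-4-5

  set.seed(53)
  tp <- random_trial_pose(60)
  s_ij <- chase_series(tp, "ind1", "ind2")
  s_ji <- chase_series(tp, "ind2", "ind1")
  expect_false(isTRUE(all.equal(s_ij$d_cm, s_ji$d_cm)))  # asymmetric
  orc <- oracle_min_pair(tp, "ind1", "ind2", "labrum", "abdomen")
  expect_equal(s_ij$d_cm, orc$d, tolerance = 1e-9)
})

test_that("pair-level chasing is the OR of the two directions", {
  n <- 1500                                 # 60 s at 25 fps
  mk <- function(d) structure(list(d_cm = d, valid = rep(TRUE, n),
                                   definition = "chase", fps = 25),
                              class = "distance_series")
  far <- mk(rep(10, n))
  expect_equal(chasing_endpoints(far, 3, s_rev = far)$pct, 0)

  near <- rep(10, n); near[1:750] <- 1      # i chases j for 30 s only
  pair <- chasing_endpoints(mk(near), 3, s_rev = far)
  expect_equal(pair$pct * n / 100 / 25, 30)
  expect_equal(pair$longest_s, 30)
})

test_that("interaction is the 25-pair minimum and contains contact", {
  set.seed(54)
  tp <- random_trial_pose(60)
  s <- interaction_series(tp, "ind1", "ind2")
  orc <- oracle_min_pair(tp, "ind1", "ind2", BODY_PARTS, BODY_PARTS)
  expect_equal(s$d_cm, orc$d, tolerance = 1e-9)

  cm <- mandible_contact_series(tp, "ind1", "ind2")
  both <- s$valid & cm$valid
  expect_true(all(s$d_cm[both] <= cm$d_cm[both] + 1e-12))
  # at equal thresholds the interaction mask contains the contact mask
  im <- interaction_endpoints(s, 3)$mask
  cmk <- contact_endpoints(cm, 3)$mask
  expect_true(all(im[cmk & both]))
})

test_that("far-apart beetles register zero interaction", {
  tp <- posed(function(e) {
    e$x[, , "ind2"] <- e$x[, , "ind2"] + 12
    e
  }, n = 20)
  s <- interaction_series(tp, "ind1", "ind2")
  expect_equal(interaction_endpoints(s, 3)$pct, 0)
})

test_that("bout extraction merges gaps and drops short runs correctly", {
  b1 <- bouts_from_mask(c(TRUE, TRUE, FALSE, TRUE, TRUE), 25,
                        merge_gap_frames = 1)
  expect_equal(nrow(b1$bouts), 1)
  expect_equal(b1$bouts$n_frames, 5)

  b0 <- bouts_from_mask(c(TRUE, TRUE, FALSE, TRUE, TRUE), 25,
                        merge_gap_frames = 0)
  expect_equal(nrow(b0$bouts), 2)
  expect_equal(b0$longest_s, 2 / 25)

  bm <- bouts_from_mask(c(TRUE, FALSE, TRUE, TRUE, TRUE), 25,
                        min_bout_frames = 2)
  expect_equal(nrow(bm$bouts), 1)
  expect_equal(bm$bouts$start_frame, 3)
})

test_that("bouts equal the run-length-encoding oracle on random masks", {
  set.seed(55)
  for (rep in 1:40) {
    n <- sample(10:200, 1)
    mask <- runif(n) < runif(1, 0.2, 0.8)
    mg <- sample(0:3, 1); mb <- sample(1:4, 1)
    got <- bouts_from_mask(mask, 25, mg, mb)$bouts
    want <- oracle_bouts(mask, mg, mb)
    expect_equal(got$start_frame, want$start)
    expect_equal(got$end_frame, want$end)
  }
})

test_that("ratios are bounded and monotone in their thresholds", {
  set.seed(56)
  n <- 400
  d <- runif(n, 0, 6)
  s <- structure(list(d_cm = d, valid = rep(TRUE, n),
                      definition = "contact", fps = 25),
                 class = "distance_series")
  thrs <- c(0.5, 1, 2, 3, 4, 6)
  below <- vapply(thrs, function(th) contact_endpoints(s, th)$pct,
                  numeric(1))
  expect_true(all(diff(below) >= 0))       # raising 'below' cutoff grows it
  above <- vapply(thrs, function(th)
    extended_mandible_ratio(s, th)$pct, numeric(1))
  expect_true(all(diff(above) <= 0))       # raising gape threshold shrinks
  expect_true(all(below >= 0 & below <= 100))
})
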