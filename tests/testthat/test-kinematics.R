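zero_pose <- function(n = 10) {
  dims <- c(n, 5, 2)
  dn <- list(NULL, BODY_PARTS, c("ind1", "ind2"))
  x <- array(3, dims, dimnames = dn)
  y <- array(3, dims, dimnames = dn)
  make_trial_pose(x, y, array(TRUE, dims, dimnames = dn))
}

test_that("reference point is the scutellum with centroid fallback", {
  tp <- zero_pose(3)
  tp$x_cm[, "scutellum", "ind1"] <- c(1, 2, 3)
  ref <- reference_point(tp, "ind1")
  expect_equal(ref$x, c(1, 2, 3))

  # scutellum invalid at frame 2: centroid of remaining valid parts
  tp$valid[2, "scutellum", "ind1"] <- FALSE
  tp$x_cm[2, c("labrum", "abdomen"), "ind1"] <- c(4, 8)
  tp$valid[2, c("left_mandible", "right_mandible"), "ind1"] <- FALSE
  ref <- reference_point(tp, "ind1")
  expect_equal(ref$x[2], mean(c(4, 8)))

  # nothing valid at a frame: the frame is invalid
  tp$valid[3, , "ind1"] <- FALSE
  ref <- reference_point(tp, "ind1")
  expect_false(ref$valid[3])
  expect_error(reference_point(tp, "nobody"), "unknown individual")
})

test_that("total distance handles stationary, unit-step and gapped tracks", {
  still <- list(x = rep(2, 10), y = rep(2, 10), valid = rep(TRUE, 10))
  expect_equal(total_distance(still), 0)

  steps <- list(x = 0:10, y = rep(0, 11), valid = rep(TRUE, 11))
  expect_equal(total_distance(steps), 10)

  # gap longer than max_gap contributes nothing
  gapped <- list(x = c(0, 1, rep(NA, 5), 10, 11),
                 y = rep(0, 9),
                 valid = c(TRUE, TRUE, rep(FALSE, 5), TRUE, TRUE))
  expect_equal(total_distance(gapped, max_gap_frames = 3), 2)
  expect_equal(total_distance(gapped, max_gap_frames = 5), 2 + 9)

  one <- list(x = 1, y = 1, valid = TRUE)
  expect_true(is.na(total_distance(one)))
})

test_that("distance and speed match the brute-force loop oracle", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(30:120, 1)
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    valid <- runif(n) < 0.85
    x[!valid] <- NA; y[!valid] <- NA
    ref <- list(x = x, y = y, valid = valid)
    mg <- sample(0:8, 1)
    expect_equal(total_distance(ref, mg),
                 oracle_total_distance(x, y, valid, mg),
                 tolerance = 1e-9)
    expect_equal(average_speed(ref, fps = 25, max_gap_frames = mg),
                 oracle_average_speed(x, y, valid, 25, mg),
                 tolerance = 1e-9)
  }
})

test_that("average speed is the duration-weighted mean on gapless input", {
  set.seed(42)
  n <- 200
  ref <- list(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
              valid = rep(TRUE, n))
  ss <- speed_series(ref, fps = 25)
  expect_equal(average_speed(ref, fps = 25), mean(ss$speed_cm_s))
  expect_equal(average_speed(list(x = c(0, 10), y = c(0, 0),
                                  valid = c(TRUE, TRUE)), fps = 1 / 600),
               10 / 600, tolerance = 1e-9)
})

test_that("movement classes partition valid time exactly", {
  still <- list(x = rep(1, 50), y = rep(1, 50), valid = rep(TRUE, 50))
  mv <- classify_movement(speed_series(still, 25))
  expect_equal(mv$freezing_s, mv$valid_s)  # all frames freezing
  expect_equal(mv$normal_s + mv$rapid_s, 0)

  set.seed(43)
  for (rep in 1:25) {
    n <- sample(20:100, 1)
    sp <- structure(list(speed_cm_s = runif(n, 0, 4),
                         valid = runif(n) < 0.9, fps = 25),
                    class = "speed_series")
    sp$speed_cm_s[!sp$valid] <- NA
    mv <- classify_movement(sp, 0.5, 2.5)
    expect_equal(mv$freezing_s + mv$normal_s + mv$rapid_s, mv$valid_s)
    counts <- oracle_classify_counts(sp$speed_cm_s, sp$valid, 0.5, 2.5)
    expect_equal(mv$freezing_s, counts[["freezing"]] / 25)
    expect_equal(mv$rapid_s, counts[["rapid"]] / 25)
  }
  expect_error(classify_movement(speed_series(still, 25), 2, 1),
               "freeze_thr")
})

test_that("distance is invariant under translation and rotation", {
  set.seed(44)
  n <- 80
  x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
  ref <- list(x = x, y = y, valid = rep(TRUE, n))
  base <- total_distance(ref)
  th <- 0.7
  rot <- list(x = cos(th) * x - sin(th) * y + 5,
              y = sin(th) * x + cos(th) * y - 3,
              valid = rep(TRUE, n))
  expect_equal(total_distance(rot), base, tolerance = 1e-9)
})

test_that("thigmotaxis counts only the boundary band", {
  meta <- trial_meta()
  centre <- list(x = rep(6.5, 10), y = rep(4, 10), valid = rep(TRUE, 10))
  expect_equal(thigmotaxis_ratio(centre, meta, 1.5), 0)
  wall <- list(x = rep(0.2, 10), y = rep(4, 10), valid = rep(TRUE, 10))
  expect_equal(thigmotaxis_ratio(wall, meta, 1.5), 100)

  set.seed(45)
  for (rep in 1:20) {
    n <- 60
    ref <- list(x = runif(n, 0, 13), y = runif(n, 0, 8),
                valid = runif(n) < 0.9)
    expect_equal(thigmotaxis_ratio(ref, meta, 1.5),
                 oracle_thigmotaxis(ref$x, ref$y, ref$valid, 13, 8, 1.5))
  }
  expect_error(thigmotaxis_ratio(centre, meta, 10), "band_cm")
})
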