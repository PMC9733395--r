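test_that("uniform resampling is exact where it should be", {
  # already-uniform input at the target rate: identical values
  tr <- min_jerk_trajectory(c(0, 0, 0), c(0.2, 0.1, 0), 1, fs = 500)
  rs <- resample_uniform(tr, 500)
  expect_equal(rs$x, tr$x, tolerance = 1e-12)
  expect_equal(rs$t, tr$t, tolerance = 1e-12)

  # linear motion interpolates exactly at any rate
  lin <- tibble::tibble(t = seq(0, 1, 0.013), x = 0.3 * seq(0, 1, 0.013),
                        y = 0, z = -0.1 * seq(0, 1, 0.013))
  rs2 <- resample_uniform(lin, 500)
  expect_equal(rs2$x, 0.3 * rs2$t, tolerance = 1e-12)
  expect_equal(rs2$z, -0.1 * rs2$t, tolerance = 1e-12)

  # minimum-jerk downsampled to 250 Hz stays within 1e-5 m of the closed form
  rs3 <- resample_uniform(tr, 250)
  expect_lt(max(abs(rs3$x - 0.2 * min_jerk_profile(rs3$t))), 1e-5)

  bad <- tr; bad$t[5] <- bad$t[4]
  expect_error(resample_uniform(bad), "strictly increasing")
})

test_that("speed profiles behave on degenerate and analytic inputs", {
  still <- tibble::tibble(t = seq(0, 1, 0.002), x = 0.1, y = 0.2, z = 0.3)
  expect_lt(max(compute_speed(still)$speed), 1e-4)

  lin <- tibble::tibble(t = seq(0, 1, 0.002), x = 0.3 * seq(0, 1, 0.002),
                        y = 0, z = 0)
  sp <- compute_speed(lin)
  interior <- sp$speed[50:450]
  expect_true(all(abs(interior - 0.3) < 1e-3))

  tr <- min_jerk_trajectory(c(0, 0, 0), c(0.3, 0, 0), 1, fs = 500)
  expect_equal(peak_velocity(compute_speed(tr)), 0.5625, tolerance = 0.01)

  expect_error(compute_speed(tibble::tibble(t = c(0, 0.004), x = 0:1, y = 0, z = 0)),
               "too short")
})

test_that("segmentation cuts appearance-to-collision windows and drops incomplete events", {
  fix <- cached_exp2_dataset()
  expect_equal(nrow(fix$segments), 720)
  expect_equal(nrow(fix$segments), nrow(fix$dataset$events))

  # single-fruit recording spans exactly [appear, collision]
  one <- fix$dataset$events[1, ]
  seg1 <- segment_movements(
    fix$dataset$samples[fix$dataset$samples$trial_id == one$trial_id, ], one)
  expect_equal(nrow(seg1), 1)
  d <- seg1$data[[1]]
  expect_gte(min(d$t), 0)
  expect_equal(max(d$t), one$collision_t - one$fruit_appear_t)
  # return-phase samples excluded
  n_return <- sum(fix$dataset$samples$trial_id == one$trial_id &
                    fix$dataset$samples$phase == "return")
  expect_gt(n_return, 0)
  expect_equal(nrow(d),
               sum(fix$dataset$samples$trial_id == one$trial_id) - n_return)

  # a missing collision drops that segment with a warning
  ev2 <- fix$dataset$events[1:3, ]
  ev2$collision_t[2] <- NA
  expect_warning(
    segs2 <- segment_movements(
      fix$dataset$samples[fix$dataset$samples$trial_id %in% ev2$trial_id, ], ev2),
    "no collision")
  expect_equal(nrow(segs2), 2)
})

test_that("collision detection respects sphere and capsule boundaries", {
  p <- build_protocol("exp1")
  orange <- p$colliders$orange
  centre <- c(0.1, 0, 0.2)
  expect_true(detect_collision(centre, 0.02, centre, orange))
  # printed diameters 10 cm and 4 cm: contact boundary at 7 cm
  expect_true(detect_collision(centre + c(0.0699, 0, 0), 0.02, centre, orange))
  expect_false(detect_collision(centre + c(0.0701, 0, 0), 0.02, centre, orange))

  pear <- p$colliders$pear
  # beyond the capsule end-cap on the axis: contact iff the axial excess is
  # within the radii sum (point-to-segment distance oracle)
  radii <- pear$capsule_diameter / 2 + 0.02
  above <- pear$capsule_height + radii
  expect_true(detect_collision(centre + c(0, above - 1e-4, 0), 0.02, centre, pear))
  expect_false(detect_collision(centre + c(0, above + 1e-4, 0), 0.02, centre, pear))
  # side of the capsule, above the lower sphere's reach
  side <- c(pear$capsule_diameter / 2 + 0.02, pear$capsule_height * 0.9, 0)
  expect_true(detect_collision(centre + side - c(1e-4, 0, 0), 0.02, centre, pear))
  expect_false(detect_collision(centre + side + c(1e-4, 0, 0), 0.02, centre, pear))
})

test_that("scalar metrics match hand-computable cases", {
  line <- tibble::tibble(t = seq(0, 1, 0.01), x = 0.5 * seq(0, 1, 0.01), y = 0, z = 0)
  expect_equal(normalized_duration(line), 2.0)
  tr <- min_jerk_trajectory(c(0, 0, 0), c(0.3, 0, 0), 0.9)
  expect_equal(normalized_duration(tr), 3.0, tolerance = 1e-9)
  still <- tibble::tibble(t = c(0, 0.5, 1), x = 0, y = 0, z = 0)
  expect_true(is.na(normalized_duration(still)))
  expect_true(is.na(straightness_ratio(still)))

  # right-angle polyline: path 2, chord sqrt(2)
  poly <- tibble::tibble(t = seq(0, 1, length.out = 201),
                         x = c(seq(0, 1, length.out = 101), rep(1, 100)),
                         y = c(rep(0, 101), seq(0.01, 1, length.out = 100)),
                         z = 0)
  expect_equal(straightness_ratio(poly), sqrt(2), tolerance = 1e-3)

  # half-circle arc: arc/chord = pi/2
  theta <- seq(0, pi, length.out = 501)
  arc <- tibble::tibble(t = seq(0, 1, length.out = 501),
                        x = cos(theta), y = sin(theta), z = 0)
  expect_equal(straightness_ratio(arc), pi / 2, tolerance = 0.005)
})

test_that("velocity-peak counting applies prominence and separation rules", {
  flat <- tibble::tibble(t = seq(0, 1, 0.002), speed = 0)
  expect_equal(count_velocity_peaks(flat), 0L)

  t <- seq(0, 1, 0.002)
  one_bell <- tibble::tibble(t = t, speed = 0.5 * sin(pi * t)^2)
  expect_equal(count_velocity_peaks(one_bell), 1L)

  two <- tibble::tibble(t = t, speed = 0.5 * exp(-((t - 0.3) / 0.07)^2) +
                          0.45 * exp(-((t - 0.7) / 0.07)^2))
  expect_equal(count_velocity_peaks(two), 2L)

  # a ripple below the prominence floor is not a peak
  ripple <- tibble::tibble(t = t, speed = 0.5 * sin(pi * t)^2 +
                             0.005 * sin(40 * pi * t))
  expect_equal(count_velocity_peaks(ripple), 1L)

  # peaks closer than the minimum separation collapse to one
  close <- tibble::tibble(t = t, speed = 0.5 * exp(-((t - 0.48) / 0.05)^2) +
                            0.5 * exp(-((t - 0.51) / 0.05)^2))
  expect_equal(count_velocity_peaks(close, min_separation = 0.05), 1L)
})

test_that("movement onset honours the threshold contract", {
  t <- seq(0, 1, 0.002)
  slow <- tibble::tibble(t = t, speed = 0.15 * sin(pi * t)^2)
  expect_true(is.na(movement_onset(slow)))
  fast_start <- tibble::tibble(t = t, speed = 0.3 - 0.1 * t)
  expect_equal(movement_onset(fast_start), 0)
  ramp <- tibble::tibble(t = t, speed = 0.4 * t)
  expect_equal(movement_onset(ramp), 0.5, tolerance = 0.002)
})

test_that("onset-absent segments are exactly those whose peak speed stays under threshold", {
  fix <- cached_exp2_dataset()
  met <- fix$metrics
  expect_identical(is.na(met$onset_s), met$peak_velocity_m_s < 0.2)
})

test_that("extreme-outlier removal matches the Tukey 3xIQR contract", {
  d <- data.frame(participant = "P01", value = c(1, 2, 3, 4, 100))
  rep1 <- remove_extreme_outliers(d, "value", "participant")
  # hand computation: Q1 = 2, Q3 = 4, IQR = 2, fences [-4, 10]
  expect_equal(rep1$fences$q1, 2)
  expect_equal(rep1$fences$q3, 4)
  expect_equal(rep1$fences$upper, 10)
  expect_equal(rep1$removed$value, 100)
  expect_equal(sort(rep1$kept$value), c(1, 2, 3, 4))

  # all equal: nothing removed
  d2 <- data.frame(participant = "P01", value = rep(5, 10))
  expect_equal(nrow(remove_extreme_outliers(d2, "value", "participant")$removed), 0)

  # values exactly on a fence are kept (strict inequality)
  d3 <- data.frame(participant = "P01", value = c(1, 2, 3, 4, 10))
  expect_equal(nrow(remove_extreme_outliers(d3, "value", "participant")$removed), 0)

  # fewer than 4 values: untouched, with a warning
  d4 <- data.frame(participant = "P01", value = c(1, 2, 1e6))
  expect_warning(rep4 <- remove_extreme_outliers(d4, "value", "participant"),
                 "fewer than 4")
  expect_equal(nrow(rep4$removed), 0)

  # grouping: fences are per participant
  d5 <- rbind(data.frame(participant = "P01", value = c(1, 2, 3, 4, 100)),
              data.frame(participant = "P02", value = c(95, 100, 105, 110)))
  rep5 <- remove_extreme_outliers(d5, "value", "participant")
  expect_equal(rep5$removed$participant, "P01")
})

test_that("outlier removal agrees with a brute-force quantile oracle", {
  withr::with_seed(99, {
    for (i in 1:60) {
      n <- sample(4:1000, 1)
      x <- switch(sample(3, 1),
                  rnorm(n), exp(rnorm(n, 0, 1.5)), rt(n, df = 2))
      d <- data.frame(participant = "P", value = x)
      rep_i <- remove_extreme_outliers(d, "value", "participant")
      expect_equal(sort(rep_i$removed$value), sort(x[oracle_outlier_flags(x)]))
    }
  })
})
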