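test_that("a session is a pure function of its seed", {
  a <- quick_archetype()
  s1 <- generate_session(a, "D01", "TD", duration = 15, seed = 123)
  s2 <- generate_session(a, "D01", "TD", duration = 15, seed = 123)
  expect_identical(s1$touch, s2$touch)
  expect_identical(s1$imu, s2$imu)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_session(s1, d1); write_session(s2, d2)
  expect_identical(readLines(file.path(d1, "touch.csv")),
                   readLines(file.path(d2, "touch.csv")))
  s3 <- generate_session(a, "D01", "TD", duration = 15, seed = 124)
  expect_false(identical(s3$touch, s1$touch))
})

test_that("generated sessions satisfy the stream invariants", {
  coh <- generate_cohort(cohort_spec(n_per_group = 2, duration = 20,
                                     seed = 6))
  expect_length(coh, 6L)
  expect_setequal(vapply(coh, function(s) s$group, character(1)),
                  c("TD", "ASD", "DCD"))
  for (s in coh) expect_true(validate_session(s))
})

test_that("tap_fraction = 1 yields only taps", {
  a <- quick_archetype(tap_fraction = 1)
  s <- generate_session(a, "TP1", "TD", duration = 30, seed = 3)
  g <- segment_gestures(s$touch)
  expect_gt(length(g), 5)
  expect_true(all(vapply(g, classify_tap, logical(1))))
})

test_that("the noiseless limit produces perfectly straight swipes", {
  a <- group_archetype(noise_sd = 0, directness_tail_sd = 0,
                       tap_fraction = 0)
  set.seed(11)
  for (i in 1:10) {
    g <- segment_gestures(generate_gesture(a, 0))[[1]]
    expect_equal(gesture_directness(g), 1, tolerance = 1e-9)
    expect_equal(kinetap:::line_deviation(g), 0, tolerance = 1e-9)
  }
})

test_that("the extracted deceleration floor recovers the generating parameter", {
  a <- group_archetype(noise_sd = 0, directness_tail_sd = 0,
                       decel_floor_sd = 0, stroke_length_sd = 0,
                       tap_fraction = 0, decel_floor_mean = -2000)
  set.seed(42)
  mins <- replicate(100, {
    g <- segment_gestures(generate_gesture(a, 0))[[1]]
    min_gesture_acceleration(kinematic_series(g))
  })
  # discretization of the minimum-jerk profile at ~60 Hz
  expect_lt(max(abs(mins + 2000)) / 2000, 0.02)
})

test_that("gesture counts track the configured rate over a 5-minute session", {
  a <- group_archetype()  # rate 0.5/s
  counts <- vapply(1:50, function(s) {
    sess <- generate_session(a, "C", "TD", duration = 300, seed = 700 + s)
    length(segment_gestures(sess$touch))
  }, numeric(1))
  expect_true(all(counts >= 100 & counts <= 200))
})

test_that("doubling attitude_sd_x raises the roll-channel variance", {
  a1 <- quick_archetype(attitude_sd_x = 0.02)
  a2 <- quick_archetype(attitude_sd_x = 0.04)
  v1 <- vapply(1:20, function(s)
    var(generate_session(a1, "A", "TD", 60, seed = 900 + s)$imu$att_x),
    numeric(1))
  v2 <- vapply(1:20, function(s)
    var(generate_session(a2, "B", "TD", 60, seed = 950 + s)$imu$att_x),
    numeric(1))
  expect_lt(wilcox.test(v1, v2, alternative = "less")$p.value, 0.01)
})

test_that("dispersion knobs map monotonically onto their features", {
  area_means <- c(); dir_means <- c()
  for (lvl in c(0.2, 0.6, 1.0)) {
    aa <- quick_archetype(area_log_sd = lvl)
    ad <- quick_archetype(directness_tail_sd = lvl * 4)
    fa <- vapply(1:6, function(s)
      extract_touch_features(
        generate_session(aa, "G", "TD", 40, seed = 80 + s))[["gesture_area_variance"]],
      numeric(1))
    fd <- vapply(1:6, function(s)
      extract_touch_features(
        generate_session(ad, "G", "TD", 40, seed = 60 + s))[["gesture_directness_variance"]],
      numeric(1))
    area_means <- c(area_means, mean(fa))
    dir_means <- c(dir_means, mean(fd))
  }
  expect_true(all(diff(area_means) > 0))
  expect_true(all(diff(dir_means) > 0))
})
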