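test_that("convex-hull gesture area matches hand cases and the brute-force oracle", {
  rect <- gesture_from_points(seq(0, 0.3, 0.1),
                              c(0, 4, 4, 0), c(0, 0, 3, 3))
  expect_equal(gesture_area(rect), 12)
  line <- gesture_from_points(seq(0, 0.4, 0.1), 0:4, 2 * (0:4))
  expect_equal(gesture_area(line), 0)
  expect_equal(gesture_area(cbind(0:1, 0:1)), 0)

  set.seed(99)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    pts <- cbind(runif(n, -5, 5), runif(n, -5, 5))
    a1 <- gesture_area(pts)
    a2 <- brute_hull_area(pts)
    expect_equal(a1, a2, tolerance = 1e-9)
  }
})

test_that("hull area is monotone non-decreasing when points are appended", {
  set.seed(17)
  pts <- cbind(runif(12), runif(12))
  areas <- vapply(3:12, function(k) gesture_area(pts[1:k, ]), numeric(1))
  expect_true(all(diff(areas) >= -1e-12))
})

test_that("directness is displacement over path length on the terminal tail", {
  straight <- gesture_from_points(seq(0, 0.5, 0.1), 0:5, rep(0, 6))
  expect_equal(gesture_directness(straight), 1)

  corner <- gesture_from_points(c(0, 0.1, 0.2), c(0, 1, 1), c(0, 0, 1))
  expect_equal(gesture_directness(corner, tail_fraction = 1), sqrt(2) / 2)

  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:15, 1)
    g <- gesture_from_points(seq(0, 1, length.out = n),
                             cumsum(rnorm(n)), cumsum(rnorm(n)))
    d <- gesture_directness(g)
    expect_gte(d, 0); expect_lte(d, 1 + 1e-12)
  }
})

test_that("minimum gesture acceleration is the signed series floor", {
  const <- kinematic_series(
    gesture_from_points(seq(0, 0.4, 0.1), seq(0, 4, 1), rep(0, 5)))
  expect_equal(min_gesture_acceleration(const), 0, tolerance = 1e-12)
  bump <- kinematic_series(
    gesture_from_points(c(0, 0.1, 0.2, 0.3), c(0, 0, 1, 1), rep(0, 4)))
  expect_equal(min_gesture_acceleration(bump), -100)
  expect_lte(min_gesture_acceleration(bump), mean(bump$accel$a))
})

test_that("the registry is frozen at 269 = 105 touch + 164 IMU unique names", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 269L)
  expect_equal(sum(reg$source == "touch"), 105L)
  expect_equal(sum(reg$source == "imu"), 164L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_true(all(canonical_features() %in% reg$name))
  expect_identical(feature_registry()$name, reg$name)
})

test_that("a session of identical gestures has zero dispersion features", {
  run1 <- touch_run(0, 0.5, n = 6, x0 = 100, y0 = 100, dx = 40, dy = 25)
  run2 <- run1; run2$t <- run2$t + 2
  s <- make_session(rbind(run1, run2), imu = flat_imu(4), duration = 4)
  v <- extract_features(s)$values
  var_feats <- grep("variance", feature_registry()$name[1:84], value = TRUE)
  expect_true(all(abs(v[var_feats]) < 1e-12))
  expect_equal(unname(v["gesture_count"]), 2)
})

test_that("dispersion features use the population variance convention", {
  expect_equal(pop_var(c(1, 1, 1)), 0)
  expect_equal(pop_var(c(0, 1, 2)), 2 / 3)
  expect_equal(pop_var(c(0, 1, 2, 3)), 1.25)
})

test_that("touch features are translation invariant except raw coordinates", {
  s <- generate_session(quick_archetype(), "T01", "TD", duration = 20,
                        seed = 13)
  s2 <- s
  s2$touch$x <- s2$touch$x + 137.5
  s2$touch$y <- s2$touch$y - 58.25
  v1 <- extract_touch_features(s)
  v2 <- extract_touch_features(s2)
  coord <- grep("^(start|end)_", names(v1), value = TRUE)
  keep <- setdiff(names(v1), coord)
  expect_equal(v2[keep], v1[keep], tolerance = 1e-8)
  expect_equal(unname(v2["start_x_mean"] - v1["start_x_mean"]), 137.5,
               tolerance = 1e-8)
})

test_that("IMU features count 164 and capture constructed signals", {
  im <- flat_imu(10)
  im$accel_y <- rep(c(0.1, -0.1), length.out = nrow(im))
  s <- make_session(touch_run(0, 0.5), imu = im, duration = 10)
  v <- extract_imu_features(s)
  expect_length(v, 164L)
  expect_equal(unname(v["attitude_variance_x"]), 0)
  # alternating sign every 0.05 s sample = 20 changes per second
  expect_equal(unname(v["accel_direction_change_rate_y"]), 20)
  tv <- extract_features(s)$values
  expect_length(tv, 269L)
  expect_equal(sum(names(tv) %in% feature_registry()$name), 269L)
})

test_that("profiles bin time-normalized kinematics with conservation", {
  # constant speed: every bin mean equal, every bin SD 0
  s <- make_session(touch_run(0, 0.9, n = 10, dx = 90), imu = flat_imu(1),
                    duration = 1)
  p <- extract_profiles(s, n_bins = 5)
  expect_equal(nrow(p), 1L)
  means <- as.numeric(p[1, paste0("speed_b", 1:5, "_mean")])
  expect_equal(means, rep(100, 5), tolerance = 1e-9)
  expect_equal(as.numeric(p[1, paste0("speed_b", 1:5, "_sd")]), rep(0, 5),
               tolerance = 1e-9)
  # 10 uniform samples -> 9 midpoint speeds; assignment arithmetic
  expect_equal(attr(p, "occupancy")$speed[1, ], c(2L, 2L, 1L, 2L, 2L))
  expect_equal(sum(attr(p, "occupancy")$speed[1, ]), 9L)
  expect_equal(sum(attr(p, "occupancy")$accel[1, ]), 8L)

  expect_error(extract_profiles(s, n_bins = 0), "n_bins")

  # conservation across many random gestures
  s2 <- generate_session(quick_archetype(), "P01", "TD", duration = 30,
                         seed = 8)
  p2 <- extract_profiles(s2, n_bins = 10)
  occ <- attr(p2, "occupancy")
  gl <- segment_gestures(s2$touch)
  expect_gt(nrow(p2), 5)
  expect_true(all(rowSums(occ$speed) == rowSums(occ$accel) + 1L))
})
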