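# Builders for hand-constructed streams and fast synthetic sessions.

# one down...move...up run; n samples on a straight line unless xs/ys given
touch_run <- function(t0, dur, n = 5, x0 = 0, y0 = 0, dx = 10, dy = 0,
                      xs = NULL, ys = NULL, pointer = 1L) {
  tt <- seq(t0, t0 + dur, length.out = n)
  data.frame(
    t = tt,
    x = xs %||% (x0 + seq(0, dx, length.out = n)),
    y = ys %||% (y0 + seq(0, dy, length.out = n)),
    phase = c("down", rep("move", n - 2), "up"),
    pointer_id = pointer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flat_imu <- function(duration = 1, rate = 20) {
  tt <- seq(0, duration, by = 1 / rate)
  data.frame(t = tt, accel_x = 0, accel_y = 0, accel_z = 0,
             rot_x = 0, rot_y = 0, rot_z = 0,
             att_x = 0, att_y = 0, att_z = 0)
}

make_session <- function(touch, imu = flat_imu(max(touch$t, 1)),
                         duration = max(c(touch$t, imu$t, 1)),
                         group = "TD", id = "S01") {
  gameplay_session(id, group, touch, imu, duration = duration)
}

# gesture object from explicit points
gesture_from_points <- function(t, x, y) {
  tr <- data.frame(t = t, x = x, y = y,
                   phase = c("down", rep("move", length(t) - 2), "up"),
                   pointer_id = 1L)
  segment_gestures(tr)[[1]]
}

# archetype tuned for fast generation in unit tests
quick_archetype <- function(...) {
  group_archetype(gesture_rate = 1.2, stroke_length_mean = 120,
                  stroke_length_sd = 30, ...)
}

# brute-force convex hull area: a segment (p, q) is a hull edge iff every
# other point lies (weakly) on one side; vertices are ordered by angle
# around the centroid and the shoelace formula applied
brute_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
          (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    if (all(cr <= 1e-12) || all(cr >= -1e-12)) {
      on_hull[i] <- TRUE; on_hull[j] <- TRUE
    }
  }
  hp <- pts[on_hull, , drop = FALSE]
  if (nrow(hp) < 3) return(0)
  ctr <- colMeans(hp)
  ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
  hp <- hp[ord, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
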