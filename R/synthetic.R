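## Synthetic gameplay: deterministic cohorts with the statistical structure
## the downstream analysis assumes. Swipes follow a minimum-jerk tangential
## velocity profile, whose acceleration extreme is analytically controlled:
## for a stroke of length L and duration T the most negative tangential
## acceleration is -(10/sqrt(3)) * L / T^2, so the generator inverts that
## relation to hit a target deceleration floor.

MIN_JERK_DECEL <- 10 / sqrt(3)  # |min s''| for unit L, T

#' Define a group archetype
#'
#' An archetype is the parameter set that generates one diagnostic group's
#' gameplay. Each canonical group-comparison feature has at least one
#' controlling knob: `area_log_sd` drives gesture-area dispersion,
#' `decel_floor_mean/sd` the per-swipe acceleration floor,
#' `directness_tail_sd` end-of-stroke curvature noise, `attitude_sd_x/y`
#' and `rot_sd_x` the device-orientation channels, and
#' `accel_dir_change_rate_y` the sign-change rate of y acceleration.
#'
#' @param name group label.
#' @param gesture_rate gestures per second.
#' @param tap_fraction proportion of gestures that are taps, in `[0, 1]`.
#' @param stroke_length_mean,stroke_length_sd swipe length (points).
#' @param area_log_sd log-scale dispersion of per-swipe bow amplitude,
#'   hence of convex-hull area.
#' @param decel_floor_mean,decel_floor_sd most negative tangential
#'   acceleration of a swipe (points/s^2; mean must be negative).
#' @param directness_tail_sd SD (points) of the terminal-phase
#'   perpendicular random walk.
#' @param attitude_sd_x,attitude_sd_y stationary SD of roll/pitch (rad).
#' @param rot_sd_x SD of x rotation rate (rad/s).
#' @param accel_dir_change_rate_y target sign-change rate of y
#'   acceleration (changes/s, < 20).
#' @param noise_sd touch sensor noise scale (points); 0 gives perfectly
#'   straight swipes.
#' @return list of class `group_archetype`.
#' @export
group_archetype <- function(name = "TD",
                            gesture_rate = 0.5,
                            tap_fraction = 0.25,
                            stroke_length_mean = 180,
                            stroke_length_sd = 60,
                            area_log_sd = 0.4,
                            decel_floor_mean = -2400,
                            decel_floor_sd = 300,
                            directness_tail_sd = 1.5,
                            attitude_sd_x = 0.02,
                            attitude_sd_y = 0.02,
                            rot_sd_x = 0.05,
                            accel_dir_change_rate_y = 6,
                            noise_sd = 1) {
  a <- structure(
    list(name = name, gesture_rate = gesture_rate,
         tap_fraction = tap_fraction,
         stroke_length_mean = stroke_length_mean,
         stroke_length_sd = stroke_length_sd, area_log_sd = area_log_sd,
         decel_floor_mean = decel_floor_mean,
         decel_floor_sd = decel_floor_sd,
         directness_tail_sd = directness_tail_sd,
         attitude_sd_x = attitude_sd_x, attitude_sd_y = attitude_sd_y,
         rot_sd_x = rot_sd_x,
         accel_dir_change_rate_y = accel_dir_change_rate_y,
         noise_sd = noise_sd),
    class = "group_archetype")
  stopifnot(a$gesture_rate > 0,
            a$tap_fraction >= 0, a$tap_fraction <= 1,
            a$stroke_length_sd >= 0, a$area_log_sd >= 0,
            a$decel_floor_mean < 0, a$decel_floor_sd >= 0,
            a$directness_tail_sd >= 0,
            a$attitude_sd_x >= 0, a$attitude_sd_y >= 0, a$rot_sd_x >= 0,
            a$accel_dir_change_rate_y > 0, a$accel_dir_change_rate_y < 20,
            a$noise_sd >= 0)
  a
}

#' @export
print.group_archetype <- function(x, ...) {
  cat("<group_archetype>", x$name, "\n")
  flds <- setdiff(names(x), "name")
  cat(paste0("  ", flds, " = ",
             vapply(x[flds], format, character(1))), sep = "\n")
  invisible(x)
}

#' Packaged archetype presets
#'
#' `"paper_like_large"` encodes the designed group contrasts: autistic
#' children show larger area dispersion, orientation (attitude/rotation)
#' variance, y-acceleration direction changes and a deeper deceleration
#' floor; children with developmental coordination disorder show noisier
#' stroke endings (directness variance), a tighter deceleration-floor
#' spread, slower gesture production and shorter strokes. `"null"` gives
#' all three groups the identical baseline archetype (for calibration
#' experiments).
#'
#' @param effect `"paper_like_large"` or `"null"`.
#' @return named list of three `group_archetype`s (TD, ASD, DCD).
#' @export
archetype_presets <- function(effect = c("paper_like_large", "null")) {
  effect <- match.arg(effect)
  td <- group_archetype(name = "TD")
  if (effect == "null") {
    asd <- td; asd$name <- "ASD"
    dcd <- td; dcd$name <- "DCD"
  } else {
    asd <- group_archetype(
      name = "ASD", area_log_sd = 0.8, decel_floor_mean = -3600,
      attitude_sd_x = 0.04, attitude_sd_y = 0.04, rot_sd_x = 0.10,
      accel_dir_change_rate_y = 10)
    dcd <- group_archetype(
      name = "DCD", gesture_rate = 0.35, tap_fraction = 0.35,
      stroke_length_mean = 140, decel_floor_mean = -1800,
      decel_floor_sd = 150, directness_tail_sd = 4,
      accel_dir_change_rate_y = 4)
  }
  list(TD = td, ASD = asd, DCD = dcd)
}

## one gesture's touch samples starting at t_start; consumes the active RNG
#' Generate one atomic gesture
#'
#' Draws either a tap (duration well under the tap threshold, near-zero
#' displacement) or a swipe: jittered ~60 Hz sampling of a minimum-jerk
#' stroke whose duration is solved from the target deceleration floor, with
#' a sinusoidal bow (lognormal amplitude scaled by `noise_sd`), a terminal
#' perpendicular random walk, and smoothed perpendicular sensor noise.
#' Uses the current RNG state (seed at the caller).
#'
#' @param archetype a `group_archetype`.
#' @param t_start gesture onset time (s).
#' @param pointer_id pointer id for the samples.
#' @return touch data frame (one down ... move ... up run).
#' @export
generate_gesture <- function(archetype, t_start = 0, pointer_id = 1L) {
  a <- archetype
  if (stats::runif(1) < a$tap_fraction) {
    dur <- stats::runif(1, 0.03, 0.10)
    x0 <- stats::runif(1, 100, 900); y0 <- stats::runif(1, 100, 650)
    n <- sample(2:4, 1)
    tt <- seq(0, dur, length.out = n)
    off <- matrix(stats::runif(2 * n, -1.5, 1.5), ncol = 2)
    off[1, ] <- 0
    return(data.frame(t = t_start + tt, x = x0 + off[, 1], y = y0 + off[, 2],
                      phase = c("down", rep("move", n - 2), "up"),
                      pointer_id = pointer_id))
  }
  L <- max(20, stats::rnorm(1, a$stroke_length_mean, a$stroke_length_sd))
  floor_mag <- max(100, stats::rnorm(1, -a$decel_floor_mean,
                                     a$decel_floor_sd))
  Tdur <- min(3, max(0.12, sqrt(MIN_JERK_DECEL * L / floor_mag)))
  tt <- 0
  repeat {
    nx <- tt[length(tt)] + (1 / 60) * stats::runif(1, 0.8, 1.2)
    if (nx >= Tdur) break
    tt <- c(tt, nx)
  }
  tt <- c(tt, Tdur)
  n <- length(tt)
  tau <- tt / Tdur
  s <- L * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  theta <- stats::runif(1, 0, 2 * pi)
  x0 <- stats::runif(1, 150, 850); y0 <- stats::runif(1, 150, 600)
  ux <- cos(theta); uy <- sin(theta)          # along-track unit vector
  px <- -uy; py <- ux                          # perpendicular unit vector
  bow_amp <- sample(c(-1, 1), 1) * a$noise_sd * 6 *
    exp(stats::rnorm(1, 0, a$area_log_sd))
  perp <- bow_amp * sin(pi * tau)
  tail_idx <- which(tau > 0.75)
  if (length(tail_idx) && a$directness_tail_sd > 0) {
    perp[tail_idx] <- perp[tail_idx] +
      cumsum(stats::rnorm(length(tail_idx), 0, a$directness_tail_sd))
  }
  if (a$noise_sd > 0 && n >= 7) {
    ## sub-point sensor jitter, smoothed so it perturbs the trajectory
    ## without drowning the tangential-acceleration floor
    raw <- stats::rnorm(n, 0, a$noise_sd * 0.5)
    sm <- stats::filter(raw, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- 0
    perp <- perp + as.numeric(sm)
  }
  data.frame(t = t_start + tt,
             x = x0 + ux * s + px * perp,
             y = y0 + uy * s + py * perp,
             phase = c("down", rep("move", n - 2), "up"),
             pointer_id = pointer_id)
}

## AR(1) with stationary SD `sd` and coefficient `rho`
ar1 <- function(n, sd, rho) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Generate a full gameplay session
#'
#' Produces a touch stream of roughly `gesture_rate * duration` gestures
#' separated by exponential pauses (pause mean solved so the target rate is
#' met on average), and a 20 Hz IMU stream: attitude channels are damped
#' (AR(1), coefficient 0.9) orientation noise at the archetype's stationary
#' SDs; rotation channels are white; the y acceleration is an AR(1) process
#' whose coefficient is chosen as `cos(pi * rate / 20)` so its expected
#' sign-change rate equals `accel_dir_change_rate_y`; every gesture onset
#' additionally injects small exponentially decaying perturbations into the
#' inertial channels (gesture-locked device reaction). The same seed always
#' yields the identical session.
#'
#' @param archetype a `group_archetype`.
#' @param subject_id,group session identity.
#' @param duration seconds (nominal 300).
#' @param seed integer seed; the session is a pure function of it.
#' @return a validated `gameplay_session`.
#' @export
generate_session <- function(archetype, subject_id, group = archetype$name,
                             duration = 300, seed = 1) {
  stopifnot(duration > 0)
  a <- archetype
  with_seed(seed, function() {
    mean_T <- sqrt(MIN_JERK_DECEL * a$stroke_length_mean /
                     -a$decel_floor_mean)
    mean_dur <- (1 - a$tap_fraction) * mean_T + a$tap_fraction * 0.065
    pause_mean <- max(0.05, 1 / a$gesture_rate - mean_dur)
    pieces <- list()
    t <- stats::rexp(1, 1 / pause_mean)
    repeat {
      g <- generate_gesture(a, t_start = t)
      t_end <- g$t[nrow(g)]
      if (t_end > duration) break
      pieces[[length(pieces) + 1L]] <- g
      t <- t_end + stats::rexp(1, 1 / pause_mean)
      if (t >= duration) break
    }
    touch <- if (length(pieces)) do.call(rbind, pieces) else empty_touch()
    starts <- vapply(pieces, function(g) g$t[1], numeric(1))

    tt <- seq(0, duration, by = 0.05)
    n <- length(tt)
    rho_y <- cos(pi * a$accel_dir_change_rate_y / 20)
    imu <- data.frame(
      t = tt,
      accel_x = stats::rnorm(n, 0, 0.02),
      accel_y = ar1(n, 0.03, rho_y),
      accel_z = stats::rnorm(n, 0, 0.02),
      rot_x = stats::rnorm(n, 0, a$rot_sd_x),
      rot_y = stats::rnorm(n, 0, 0.02),
      rot_z = stats::rnorm(n, 0, 0.02),
      att_x = ar1(n, a$attitude_sd_x, 0.9),
      att_y = ar1(n, a$attitude_sd_y, 0.9),
      att_z = ar1(n, 0.01, 0.9))
    for (t0 in starts) {
      idx <- which(tt >= t0 & tt <= t0 + 0.4)
      if (!length(idx)) next
      decay <- exp(-(tt[idx] - t0) / 0.08)
      ramp <- (tt[idx] - t0) * exp(-(tt[idx] - t0) / 0.1)
      imu$accel_x[idx] <- imu$accel_x[idx] + stats::rnorm(1, 0, 0.02) * decay
      imu$accel_z[idx] <- imu$accel_z[idx] + stats::rnorm(1, 0, 0.02) * decay
      imu$rot_y[idx] <- imu$rot_y[idx] + stats::rnorm(1, 0, 0.01) * decay
      imu$att_x[idx] <- imu$att_x[idx] + stats::rnorm(1, 0, 0.004) * ramp
      imu$att_y[idx] <- imu$att_y[idx] + stats::rnorm(1, 0, 0.004) * ramp
    }
    gameplay_session(subject_id = subject_id, group = group,
                     touch = touch, imu = imu, duration = duration)
  })
}

#' Specify a synthetic cohort
#'
#' @param archetypes named list of `group_archetype`s (names are group
#'   labels).
#' @param n_per_group sessions per group (>= 1).
#' @param duration session length (s).
#' @param seed master seed; per-subject seeds are derived from it by a
#'   counter, so the cohort is reproducible and stable under resizing.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(archetypes = archetype_presets("paper_like_large"),
                        n_per_group = 20, duration = 300, seed = 1) {
  stopifnot(n_per_group >= 1, length(archetypes) >= 1,
            !is.null(names(archetypes)))
  structure(list(archetypes = archetypes, n_per_group = n_per_group,
                 duration = duration, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of sessions
#'
#' @param spec a `cohort_spec`.
#' @return list of `gameplay_session`s, `n_per_group` per group.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sessions <- list()
  idx <- 0L
  for (gname in names(spec$archetypes)) {
    for (i in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", gname, i)
      sessions[[sid]] <- generate_session(
        spec$archetypes[[gname]], subject_id = sid, group = gname,
        duration = spec$duration, seed = derive_seed(spec$seed, idx))
    }
  }
  sessions
}
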