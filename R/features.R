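## Feature extraction: 269 session features + per-movement bin profiles.

touch_agg <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    return(stats::setNames(rep(NA_real_, length(TOUCH_STATS)), TOUCH_STATS))
  c(mean = mean(x), variance = pop_var(x), min = min(x), max = max(x),
    median = stats::median(x), q1 = q1(x), q3 = q3(x))
}

#' Extract the 105 touch features of a session
#'
#' The touch stream is segmented into atomic gestures; taps
#' (duration < `dur_thresh`, displacement < `disp_thresh`) and degenerate
#' gestures (< 3 samples) are counted but excluded from kinematic
#' aggregates, which are computed over swipes only. Each per-gesture base
#' quantity (duration, path length, displacement, convex-hull area,
#' terminal directness, chord deviation, mean/max/min speed, mean/min/max
#' tangential acceleration) is reduced to its session statistics (mean,
#' population variance, min, max, median, Q1, Q3). `minimum_gesture_acceleration`
#' is the session mean of the per-swipe acceleration floor. Aggregate
#' features of a session with no eligible gestures are the missing-value
#' sentinel `NA` (never silent zero); count features are 0.
#'
#' @param session a `gameplay_session`.
#' @param dur_thresh,disp_thresh tap thresholds (s, points).
#' @param tail_fraction terminal fraction of samples for directness.
#' @param pointer pointer selection, see [segment_gestures()].
#' @param smooth smoothing flag for [kinematic_series()].
#' @return named numeric vector of length 105, in registry order.
#' @export
extract_touch_features <- function(session, dur_thresh = 0.15,
                                   disp_thresh = 10, tail_fraction = 0.25,
                                   pointer = "first", smooth = FALSE) {
  gestures <- segment_gestures(session$touch, pointer = pointer)
  n_g <- length(gestures)
  is_tap <- vapply(gestures, classify_tap, logical(1),
                   dur_thresh = dur_thresh, disp_thresh = disp_thresh)
  degen <- vapply(gestures, function(g) g$degenerate, logical(1))
  swipes <- gestures[!is_tap & !degen]
  swipes <- lapply(swipes, kinematic_series, smooth = smooth)
  swipes <- Filter(function(g) nrow(g$accel) > 0 && g$duration > 0, swipes)

  per <- function(fn) vapply(swipes, fn, numeric(1))
  q <- list(
    gesture_duration = per(function(g) g$duration),
    gesture_path_length = per(function(g) g$path_length),
    gesture_displacement = per(function(g) g$displacement),
    gesture_area = per(gesture_area),
    gesture_directness = per(function(g)
      gesture_directness(g, tail_fraction)),
    gesture_line_deviation = per(line_deviation),
    gesture_mean_speed = per(function(g) mean(g$speed$v)),
    gesture_max_speed = per(function(g) max(g$speed$v)),
    gesture_min_speed = per(function(g) min(g$speed$v)),
    gesture_mean_accel = per(function(g) mean(g$accel$a)),
    gesture_min_accel = per(function(g) min(g$accel$a)),
    gesture_max_accel = per(function(g) max(g$accel$a)))

  out <- numeric(0)
  for (qn in TOUCH_QUANTITIES) {
    ag <- touch_agg(q[[qn]])
    names(ag) <- touch_feature_name(qn, TOUCH_STATS)
    out <- c(out, ag)
  }

  first_pt <- function(g, col) g$samples[[col]][1]
  last_pt <- function(g, col) g$samples[[col]][nrow(g$samples)]
  sx <- vapply(gestures, first_pt, numeric(1), "x")
  sy <- vapply(gestures, first_pt, numeric(1), "y")
  ex <- vapply(gestures, last_pt, numeric(1), "x")
  ey <- vapply(gestures, last_pt, numeric(1), "y")
  mo <- function(v) if (length(v)) mean(v) else NA_real_
  so <- function(v) if (length(v)) pop_sd(v) else NA_real_
  out <- c(out, start_x_mean = mo(sx), start_x_sd = so(sx),
           start_y_mean = mo(sy), start_y_sd = so(sy),
           end_x_mean = mo(ex), end_x_sd = so(ex),
           end_y_mean = mo(ey), end_y_sd = so(ey))

  # gaps from each gesture's up to the next gesture's down
  if (n_g >= 2) {
    ends <- vapply(gestures, function(g) g$samples$t[nrow(g$samples)],
                   numeric(1))
    starts <- vapply(gestures, function(g) g$samples$t[1], numeric(1))
    gaps <- starts[-1] - ends[-n_g]
  } else gaps <- numeric(0)
  gi <- if (length(gaps))
    c(mean = mean(gaps), sd = pop_sd(gaps), min = min(gaps),
      max = max(gaps), median = stats::median(gaps))
  else stats::setNames(rep(NA_real_, 5), c("mean", "sd", "min", "max",
                                           "median"))
  names(gi) <- paste0("intergesture_interval_", names(gi))
  out <- c(out, gi)

  tap_starts <- vapply(gestures[is_tap], function(g) g$samples$t[1],
                       numeric(1))
  iti <- if (length(tap_starts) >= 2) diff(sort(tap_starts)) else numeric(0)
  dur <- session$duration
  out <- c(out,
           tap_count = sum(is_tap),
           tap_rate = if (dur > 0) sum(is_tap) / dur else NA_real_,
           tap_fraction = if (n_g > 0) sum(is_tap) / n_g else NA_real_,
           gesture_count = n_g,
           swipe_count = length(swipes),
           intertap_interval_mean = if (length(iti)) mean(iti) else NA_real_,
           intertap_interval_sd = if (length(iti)) pop_sd(iti) else NA_real_,
           intertap_interval_min = if (length(iti)) min(iti) else NA_real_)
  reg <- feature_registry()
  out[reg$name[reg$source == "touch"]]
}

imu_channel_stats <- function(x) {
  if (length(x) == 0L || all(!is.finite(x)))
    return(stats::setNames(rep(NA_real_, length(IMU_STATS)), IMU_STATS))
  x <- x[is.finite(x)]
  c(mean = mean(x), sd = pop_sd(x), variance = pop_var(x), min = min(x),
    max = max(x), median = stats::median(x), q1 = q1(x), q3 = q3(x),
    range = max(x) - min(x), iqr = q3(x) - q1(x))
}

sign_change_rate <- function(x, t) {
  s <- sign(x)
  s <- s[s != 0]
  span <- t[length(t)] - t[1]
  if (length(s) < 2 || span <= 0) return(NA_real_)
  sum(diff(s) != 0) / span
}

#' Extract the 164 IMU features of a session
#'
#' Inertial features are computed across the whole session irrespective of
#' the touch stream. For each of the four channels — acceleration, rotation
#' rate, attitude, and jerk (the timestamped first difference of
#' acceleration) — and each of the four axes (x, y, z and the Euclidean
#' magnitude), ten session statistics are computed (mean, SD, population
#' variance, min, max, median, Q1, Q3, range, IQR). The per-axis
#' acceleration-direction change rate is the number of sign changes of that
#' acceleration component per second. An empty IMU stream yields sentinel
#' `NA`s with a warning.
#'
#' @param session a `gameplay_session`.
#' @return named numeric vector of length 164, in registry order.
#' @export
extract_imu_features <- function(session) {
  im <- session$imu
  reg <- feature_registry()
  imu_names <- reg$name[reg$source == "imu"]
  if (nrow(im) == 0L) {
    warning("empty IMU stream for subject ", session$subject_id,
            "; IMU features set to NA")
    out <- stats::setNames(rep(NA_real_, length(imu_names)), imu_names)
    out["imu_sample_count"] <- 0
    return(out)
  }
  mag <- function(a, b, c) sqrt(a^2 + b^2 + c^2)
  dt <- diff(im$t)
  jerk <- lapply(c("accel_x", "accel_y", "accel_z"),
                 function(cn) diff(im[[cn]]) / dt)
  series <- list(
    accel = list(x = im$accel_x, y = im$accel_y, z = im$accel_z,
                 mag = mag(im$accel_x, im$accel_y, im$accel_z)),
    rotation = list(x = im$rot_x, y = im$rot_y, z = im$rot_z,
                    mag = mag(im$rot_x, im$rot_y, im$rot_z)),
    attitude = list(x = im$att_x, y = im$att_y, z = im$att_z,
                    mag = mag(im$att_x, im$att_y, im$att_z)),
    jerk = list(x = jerk[[1]], y = jerk[[2]], z = jerk[[3]],
                mag = mag(jerk[[1]], jerk[[2]], jerk[[3]])))
  out <- numeric(0)
  for (ch in IMU_CHANNELS) {
    for (ax in IMU_AXES) {
      st <- imu_channel_stats(series[[ch]][[ax]])
      names(st) <- paste(ch, IMU_STATS, ax, sep = "_")
      out <- c(out, st)
    }
  }
  out <- c(out,
           accel_direction_change_rate_x = sign_change_rate(im$accel_x, im$t),
           accel_direction_change_rate_y = sign_change_rate(im$accel_y, im$t),
           accel_direction_change_rate_z = sign_change_rate(im$accel_z, im$t),
           imu_sample_count = nrow(im))
  out[imu_names]
}

#' Extract the full 269-feature session representation
#'
#' @inheritParams extract_touch_features
#' @return a `feature_vector`: list with `subject_id`, `group` and a named
#'   numeric `values` of length 269 (105 touch + 164 IMU, registry order).
#' @export
extract_features <- function(session, dur_thresh = 0.15, disp_thresh = 10,
                             tail_fraction = 0.25, pointer = "first",
                             smooth = FALSE) {
  vals <- c(extract_touch_features(session, dur_thresh, disp_thresh,
                                   tail_fraction, pointer, smooth),
            extract_imu_features(session))
  structure(list(subject_id = session$subject_id, group = session$group,
                 values = vals),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector>", x$subject_id, sprintf("(%s):", x$group),
      length(x$values), "features,", sum(!is.finite(x$values)),
      "missing\n")
  invisible(x)
}

PROFILE_STATS <- c("mean", "median", "sd", "q1", "q3")

bin_stats <- function(v) {
  c(mean = mean(v), median = stats::median(v), sd = pop_sd(v),
    q1 = q1(v), q3 = q3(v))
}

#' Per-movement time-normalized bin profiles
#'
#' Each swipe is an independent training sample carrying its session's
#' label. Because movements differ in duration and sample count, each
#' movement's kinematic sample times are normalized to `[0, 1]` (gesture
#' start 0, end 1) and assigned to `n_bins` left-closed half-open bins (the
#' last bin closed). Per bin and per series (speed; tangential
#' acceleration) five statistics are computed: mean, median, SD, Q1, Q3.
#' Empty bins are imputed with the movement-level statistic and flagged in
#' the `imputed` attribute; occupancy counts are kept in the `occupancy`
#' attribute and sum to each series' sample count.
#'
#' @param session a `gameplay_session`.
#' @param n_bins number of time bins (>= 1).
#' @inheritParams extract_touch_features
#' @return data frame of class `profile_table`: `subject_id`, `group`,
#'   `gesture`, then `n_bins * 5 * 2` feature columns; attributes
#'   `occupancy` (list of speed/accel count matrices) and `imputed`.
#' @export
extract_profiles <- function(session, n_bins = 10, dur_thresh = 0.15,
                             disp_thresh = 10, pointer = "first",
                             smooth = FALSE) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  gestures <- segment_gestures(session$touch, pointer = pointer)
  keep <- vapply(gestures, function(g)
    !g$degenerate && !classify_tap(g, dur_thresh, disp_thresh), logical(1))
  gestures <- lapply(gestures[keep], kinematic_series, smooth = smooth)
  gestures <- Filter(function(g) nrow(g$speed) >= 1 && nrow(g$accel) >= 1 &&
                       g$duration > 0, gestures)
  cols <- as.vector(outer(PROFILE_STATS,
                          outer(paste0("b", seq_len(n_bins)),
                                c("speed", "accel"),
                                function(b, s) paste(s, b, sep = "_")),
                          function(st, pre) paste(pre, st, sep = "_")))
  n_mov <- length(gestures)
  mat <- matrix(NA_real_, n_mov, length(cols), dimnames = list(NULL, cols))
  occ_speed <- matrix(0L, n_mov, n_bins)
  occ_accel <- matrix(0L, n_mov, n_bins)
  imputed <- matrix(FALSE, n_mov, 2 * n_bins)
  for (i in seq_len(n_mov)) {
    g <- gestures[[i]]
    t0 <- g$samples$t[1]; t1 <- g$samples$t[nrow(g$samples)]
    for (series in c("speed", "accel")) {
      dfs <- g[[series]]
      val <- if (series == "speed") dfs$v else dfs$a
      tau <- (dfs$t - t0) / (t1 - t0)
      bin <- pmin(floor(tau * n_bins) + 1L, n_bins)
      whole <- bin_stats(val)
      for (b in seq_len(n_bins)) {
        inb <- val[bin == b]
        nb <- length(inb)
        if (series == "speed") occ_speed[i, b] <- nb else
          occ_accel[i, b] <- nb
        st <- if (nb > 0) bin_stats(inb) else whole
        if (nb == 0)
          imputed[i, (if (series == "speed") 0L else n_bins) + b] <- TRUE
        mat[i, paste(series, paste0("b", b), PROFILE_STATS,
                     sep = "_")] <- st
      }
    }
  }
  df <- data.frame(subject_id = rep(session$subject_id, n_mov),
                   group = rep(session$group, n_mov),
                   gesture = seq_len(n_mov),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  attr(df, "occupancy") <- list(speed = occ_speed, accel = occ_accel)
  attr(df, "imputed") <- imputed
  class(df) <- c("profile_table", "data.frame")
  df
}
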