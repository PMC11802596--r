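#' Segment a touch stream into atomic gestures
#'
#' An atomic gesture is one touch-down ... move ... touch-up run by a single
#' pointer; it is the unit of all kinematic analysis. Samples are assigned to
#' exactly one gesture. A trailing down without an up closes the gesture at
#' the last sample with a warning. Gestures with fewer than 3 samples are
#' retained and flagged degenerate (their derivatives are undefined).
#'
#' @param touch touch data frame (see [gameplay_session()]).
#' @param pointer `"first"` (default, dominant-hand assumption: only the
#'   first pointer id seen) or `"all"`.
#' @return list of `gesture` objects, in temporal order.
#' @export
segment_gestures <- function(touch, pointer = c("first", "all")) {
  pointer <- match.arg(pointer)
  if (nrow(touch) == 0L) return(list())
  if (pointer == "first") {
    touch <- touch[touch$pointer_id == touch$pointer_id[1], , drop = FALSE]
  }
  gestures <- list()
  for (p in unique(touch$pointer_id)) {
    sub <- touch[touch$pointer_id == p, , drop = FALSE]
    starts <- which(sub$phase == "down")
    ends <- which(sub$phase == "up")
    for (k in seq_along(starts)) {
      s <- starts[k]
      e <- ends[ends >= s]
      if (length(e) == 0L) {
        warning("unmatched down at stream end (pointer ", p,
                "); gesture closed at last sample")
        e <- nrow(sub)
      } else e <- e[1]
      gestures[[length(gestures) + 1L]] <-
        new_gesture(sub[s:e, , drop = FALSE])
    }
  }
  ord <- order(vapply(gestures, function(g) g$samples$t[1], numeric(1)))
  gestures[ord]
}

new_gesture <- function(samples) {
  n <- nrow(samples)
  disp <- if (n >= 2)
    sqrt((samples$x[n] - samples$x[1])^2 + (samples$y[n] - samples$y[1])^2)
  else 0
  path <- if (n >= 2) sum(sqrt(diff(samples$x)^2 + diff(samples$y)^2)) else 0
  structure(
    list(samples = samples,
         duration = samples$t[n] - samples$t[1],
         path_length = path,
         displacement = disp,
         degenerate = n < 3,
         is_tap = NA,
         speed = NULL,     # data.frame(t, v): per-interval speed at midpoints
         accel = NULL),    # data.frame(t, a): tangential acceleration
    class = "gesture")
}

#' @export
print.gesture <- function(x, ...) {
  cat(sprintf("<gesture> %d samples, %.3f s, path %.1f pt, disp %.1f pt%s\n",
              nrow(x$samples), x$duration, x$path_length, x$displacement,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Classify a gesture as a tap
#'
#' A tap is a degenerate contact: short and nearly stationary. The predicate
#' is `duration < dur_thresh AND displacement < disp_thresh` (both strict).
#' Defaults (0.15 s, 10 points) are pipeline configuration.
#'
#' @param g a `gesture`.
#' @param dur_thresh seconds.
#' @param disp_thresh screen points.
#' @return logical scalar.
#' @export
classify_tap <- function(g, dur_thresh = 0.15, disp_thresh = 10) {
  g$duration < dur_thresh && g$displacement < disp_thresh
}

#' Compute per-sample kinematic series for a gesture
#'
#' Speeds are actual-timestamp finite differences (no resampling, since the
#' touch rate is variable): `speed_i = ||p_{i+1} - p_i|| / (t_{i+1} - t_i)`,
#' stamped at the interval midpoint. Signed tangential acceleration is the
#' finite difference of speed over midpoint timestamps, so its minimum
#' captures peak deceleration. Optional 3-point moving-average smoothing of
#' the coordinates (default off) is available for noisy inputs.
#'
#' @param g a `gesture` with at least 2 samples.
#' @param smooth apply 3-point moving-average smoothing to x,y first.
#' @return the gesture with `speed` and `accel` populated.
#' @export
kinematic_series <- function(g, smooth = FALSE) {
  s <- g$samples
  n <- nrow(s)
  if (n < 2) stop("kinematic series need at least 2 samples")
  if (anyDuplicated(s$t))
    stop("duplicate timestamps within gesture starting at t=", s$t[1])
  x <- s$x; y <- s$y
  if (smooth && n >= 3) {
    x <- stats::filter(x, rep(1 / 3, 3), sides = 2)
    y <- stats::filter(y, rep(1 / 3, 3), sides = 2)
    x[1] <- s$x[1]; x[n] <- s$x[n]; y[1] <- s$y[1]; y[n] <- s$y[n]
    x <- as.numeric(x); y <- as.numeric(y)
  }
  dt <- diff(s$t)
  v <- sqrt(diff(x)^2 + diff(y)^2) / dt
  tm <- (s$t[-1] + s$t[-n]) / 2
  g$speed <- data.frame(t = tm, v = v)
  if (n >= 3) {
    a <- diff(v) / diff(tm)
    g$accel <- data.frame(t = (tm[-1] + tm[-(n - 1)]) / 2, a = a)
  } else {
    g$accel <- data.frame(t = numeric(), a = numeric())
  }
  g
}

## per-gesture scalar kinematics used by the feature engine -----------------

#' Convex-hull area of a gesture's touch points
#'
#' The gesture area is the area of the minimal convex polygon around the
#' stroke (shoelace formula over the convex hull). It is 0 for two or fewer
#' points and for collinear points.
#'
#' @param g a `gesture`, or a two-column matrix/data frame of points.
#' @return area in points^2.
#' @export
gesture_area <- function(g) {
  pts <- if (inherits(g, "gesture")) cbind(g$samples$x, g$samples$y)
         else as.matrix(g)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(0)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Directness of the terminal stroke segment
#'
#' Ratio of straight-line displacement to path length over the final
#' `tail_fraction` of the gesture's samples; 1 means a perfectly straight
#' (smooth) ending, smaller values a curved or jittery one. A stationary
#' tail (zero path length) is defined as perfectly direct (1).
#'
#' @param g a `gesture` with at least 2 samples.
#' @param tail_fraction fraction of samples forming the terminal segment.
#' @return directness in `[0, 1]`.
#' @export
gesture_directness <- function(g, tail_fraction = 0.25) {
  s <- g$samples
  n <- nrow(s)
  if (n < 2) stop("directness needs at least 2 samples")
  m <- max(2L, ceiling(tail_fraction * n))
  tail <- s[(n - m + 1L):n, , drop = FALSE]
  path <- sum(sqrt(diff(tail$x)^2 + diff(tail$y)^2))
  if (path == 0) return(1)
  disp <- sqrt((tail$x[m] - tail$x[1])^2 + (tail$y[m] - tail$y[1])^2)
  disp / path
}

#' Minimum (most negative) tangential acceleration of a gesture
#'
#' The floor of the signed tangential acceleration series: the gesture's
#' peak deceleration.
#'
#' @param g a `gesture`; series are computed on the fly if absent.
#' @return points/s^2.
#' @export
min_gesture_acceleration <- function(g) {
  if (is.null(g$accel)) g <- kinematic_series(g)
  if (nrow(g$accel) == 0L)
    stop("gesture too short for an acceleration series")
  min(g$accel$a)
}

#' Maximum perpendicular deviation from the gesture chord
#'
#' Distance of the farthest sample from the straight line joining the
#' gesture's first and last points; 0 for a straight stroke.
#'
#' @param g a `gesture`.
#' @return points.
#' @keywords internal
line_deviation <- function(g) {
  s <- g$samples
  n <- nrow(s)
  if (n < 3) return(0)
  dx <- s$x[n] - s$x[1]; dy <- s$y[n] - s$y[1]
  L <- sqrt(dx^2 + dy^2)
  if (L == 0) {
    return(max(sqrt((s$x - s$x[1])^2 + (s$y - s$y[1])^2)))
  }
  max(abs(dy * (s$x - s$x[1]) - dx * (s$y - s$y[1])) / L)
}
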