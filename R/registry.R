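## The session representation is a frozen, versioned inventory of exactly
## 269 named features: 105 derived from the touch trajectories and 164 from
## the IMU streams. The inventory is built as {base quantity} x {statistic}
## grids; a handful of canonical names (the ones reported in group
## comparisons) override the mechanical naming.

TOUCH_QUANTITIES <- c(
  "gesture_duration", "gesture_path_length", "gesture_displacement",
  "gesture_area", "gesture_directness", "gesture_line_deviation",
  "gesture_mean_speed", "gesture_max_speed", "gesture_min_speed",
  "gesture_mean_accel", "gesture_min_accel", "gesture_max_accel")

TOUCH_STATS <- c("mean", "variance", "min", "max", "median", "q1", "q3")

COORD_FEATURES <- c("start_x_mean", "start_x_sd", "start_y_mean",
                    "start_y_sd", "end_x_mean", "end_x_sd",
                    "end_y_mean", "end_y_sd")

INTERVAL_FEATURES <- c("intergesture_interval_mean", "intergesture_interval_sd",
                       "intergesture_interval_min", "intergesture_interval_max",
                       "intergesture_interval_median")

TAP_FEATURES <- c("tap_count", "tap_rate", "tap_fraction", "gesture_count",
                  "swipe_count", "intertap_interval_mean",
                  "intertap_interval_sd", "intertap_interval_min")

IMU_CHANNELS <- c("accel", "rotation", "attitude", "jerk")
IMU_AXES <- c("x", "y", "z", "mag")
IMU_STATS <- c("mean", "sd", "variance", "min", "max", "median",
               "q1", "q3", "range", "iqr")

## mechanical name -> canonical reported name
TOUCH_NAME_OVERRIDES <- c(gesture_min_accel_mean = "minimum_gesture_acceleration")

touch_feature_name <- function(quantity, stat) {
  nm <- paste(quantity, stat, sep = "_")
  unname(ifelse(nm %in% names(TOUCH_NAME_OVERRIDES),
                TOUCH_NAME_OVERRIDES[nm], nm))
}

.registry_cache <- new.env(parent = emptyenv())

#' The frozen 269-feature registry
#'
#' Returns the ordered inventory of session features: 105 touch features
#' (12 per-gesture kinematic quantities x 7 session statistics, start/end
#' coordinate statistics, inter-gesture interval statistics, and tap/count
#' features) and 164 IMU features (4 channels x 4 axes x 10 statistics,
#' per-axis acceleration-direction sign-change rates, and the sample count).
#' Column order of every feature table is this registry's order, never
#' insertion order. The seven canonical group-comparison features
#' (`attitude_variance_x`, `attitude_variance_y`, `gesture_area_variance`,
#' `minimum_gesture_acceleration`, `accel_direction_change_rate_y`,
#' `rotation_variance_x`, `gesture_directness_variance`) are fixed entries.
#'
#' @return data frame with columns `name`, `source` (`touch`/`imu`),
#'   `quantity`, `stat`; 269 rows.
#' @export
feature_registry <- function() {
  if (!is.null(.registry_cache$reg)) return(.registry_cache$reg)
  grid <- expand.grid(stat = TOUCH_STATS, quantity = TOUCH_QUANTITIES,
                      stringsAsFactors = FALSE)[, c("quantity", "stat")]
  touch <- data.frame(
    name = c(touch_feature_name(grid$quantity, grid$stat),
             COORD_FEATURES, INTERVAL_FEATURES, TAP_FEATURES),
    source = "touch",
    quantity = c(grid$quantity,
                 sub("_(mean|sd)$", "", COORD_FEATURES),
                 rep("intergesture_interval", length(INTERVAL_FEATURES)),
                 TAP_FEATURES),
    stat = c(grid$stat,
             sub("^.*_(mean|sd)$", "\\1", COORD_FEATURES),
             sub("^intergesture_interval_", "", INTERVAL_FEATURES),
             rep("scalar", length(TAP_FEATURES))),
    stringsAsFactors = FALSE)
  igrid <- expand.grid(stat = IMU_STATS, axis = IMU_AXES,
                       channel = IMU_CHANNELS, stringsAsFactors = FALSE)
  imu <- data.frame(
    name = c(paste(igrid$channel, igrid$stat, igrid$axis, sep = "_"),
             paste0("accel_direction_change_rate_", c("x", "y", "z")),
             "imu_sample_count"),
    source = "imu",
    quantity = c(paste(igrid$channel, igrid$axis, sep = "_"),
                 paste0("accel_", c("x", "y", "z")), "imu_samples"),
    stat = c(igrid$stat, rep("sign_change_rate", 3), "count"),
    stringsAsFactors = FALSE)
  reg <- rbind(touch, imu)
  stopifnot(sum(reg$source == "touch") == 105L,
            sum(reg$source == "imu") == 164L,
            nrow(reg) == 269L, !anyDuplicated(reg$name))
  .registry_cache$reg <- reg
  reg
}

#' Names of the seven canonical group-comparison features
#' @return character vector of length 7.
#' @export
canonical_features <- function() {
  c("attitude_variance_x", "gesture_area_variance",
    "minimum_gesture_acceleration", "accel_direction_change_rate_y",
    "rotation_variance_x", "attitude_variance_y",
    "gesture_directness_variance")
}
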