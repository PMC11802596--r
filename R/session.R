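#' Construct a gameplay session
#'
#' A session bundles the two raw sensor streams recorded while a child plays
#' the tablet coloring game for (nominally) five minutes: the touch stream
#' (timestamped screen coordinates with down/move/up phases, variable rate
#' around 60 Hz) and the IMU stream (triaxial acceleration, rotation rate and
#' attitude at a regular rate around 20 Hz), plus the subject's identity,
#' diagnostic group and covariates.
#'
#' Timestamps are seconds since session start. Screen coordinates are
#' abstract points with the origin top-left and y increasing downward (the
#' touch-device convention).
#'
#' @param subject_id character scalar.
#' @param group one of `"TD"`, `"ASD"`, `"DCD"`.
#' @param touch data frame with columns `t`, `x`, `y`, `phase`
#'   (`"down"`/`"move"`/`"up"`) and `pointer_id`.
#' @param imu data frame with columns `t`, `accel_x/y/z` (m/s^2),
#'   `rot_x/y/z` (rad/s), `att_x/y/z` (rad, roll/pitch/yaw).
#' @param duration session length in seconds (nominal 300).
#' @param covariates named list of subject covariates (age, IQ, motor
#'   scores, ...).
#' @return an object of class `gameplay_session`.
#' @export
gameplay_session <- function(subject_id, group, touch, imu,
                             duration = 300, covariates = list()) {
  s <- structure(
    list(subject_id = as.character(subject_id),
         group = as.character(group),
         duration = as.numeric(duration),
         covariates = covariates,
         touch = as.data.frame(touch),
         imu = as.data.frame(imu)),
    class = "gameplay_session")
  validate_session(s)
  s
}

TOUCH_COLS <- c("t", "x", "y", "phase", "pointer_id")
IMU_COLS <- c("t", "accel_x", "accel_y", "accel_z",
              "rot_x", "rot_y", "rot_z", "att_x", "att_y", "att_z")

empty_touch <- function() {
  data.frame(t = numeric(), x = numeric(), y = numeric(),
             phase = character(), pointer_id = integer())
}

empty_imu <- function() {
  as.data.frame(stats::setNames(rep(list(numeric()), length(IMU_COLS)),
                                IMU_COLS))
}

#' Validate a gameplay session
#'
#' Checks the stream invariants: required columns, group label, timestamps
#' inside `[0, duration]`, IMU timestamps strictly increasing, touch
#' timestamps non-decreasing within each pointer, legal phase values and,
#' per pointer, that no up/move precedes a down and every down is eventually
#' matched by an up.
#'
#' @param session a `gameplay_session`.
#' @return invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "gameplay_session"))
  if (!session$group %in% GROUP_LEVELS)
    stop("group label must be one of ", paste(GROUP_LEVELS, collapse = ", "),
         "; got '", session$group, "'")
  miss <- setdiff(TOUCH_COLS, names(session$touch))
  if (length(miss)) stop("touch stream missing columns: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(IMU_COLS, names(session$imu))
  if (length(miss)) stop("imu stream missing columns: ",
                         paste(miss, collapse = ", "))
  tt <- session$touch
  if (nrow(tt)) {
    if (any(!tt$phase %in% c("down", "move", "up")))
      stop("touch phase values must be down/move/up")
    if (any(tt$t < 0) || any(tt$t > session$duration + 1e-9))
      stop("touch timestamps outside [0, duration]")
    for (p in unique(tt$pointer_id)) {
      sub <- tt[tt$pointer_id == p, ]
      bad <- which(diff(sub$t) < 0)
      if (length(bad))
        stop("non-monotone touch timestamps for pointer ", p,
             " at row ", bad[1] + 1L)
      state <- 0L  # 0 = up, 1 = down
      for (i in seq_len(nrow(sub))) {
        ph <- sub$phase[i]
        if (ph == "down") {
          if (state == 1L) stop("pointer ", p, ": down while already down",
                                " at row ", i)
          state <- 1L
        } else {
          if (state == 0L) stop("pointer ", p, ": '", ph,
                                "' before any down at row ", i)
          if (ph == "up") state <- 0L
        }
      }
    }
  }
  im <- session$imu
  if (nrow(im)) {
    if (any(im$t < 0) || any(im$t > session$duration + 1e-9))
      stop("imu timestamps outside [0, duration]")
    bad <- which(diff(im$t) <= 0)
    if (length(bad))
      stop("imu timestamps not strictly increasing at row ", bad[1] + 1L)
  }
  invisible(TRUE)
}

#' @export
print.gameplay_session <- function(x, ...) {
  cat("<gameplay_session> subject", x$subject_id,
      sprintf("(%s), %.0f s", x$group, x$duration), "\n")
  cat("  touch:", nrow(x$touch), "samples | imu:", nrow(x$imu), "samples\n")
  if (length(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Read a session bundle from disk
#'
#' A session bundle is a directory holding `session.json` (subject id, group,
#' duration, covariates, stream filenames) plus `touch.csv` and `imu.csv`
#' (RFC-4180, UTF-8, '.' decimal separator). The session is validated on
#' load.
#'
#' @param path directory written by [write_session()].
#' @return a `gameplay_session`.
#' @export
read_session <- function(path) {
  manifest_path <- file.path(path, "session.json")
  if (!file.exists(manifest_path))
    stop("no session.json under ", path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  touch <- utils::read.csv(file.path(path, man$touch_file %||% "touch.csv"),
                           colClasses = "character")
  if (!setequal(names(touch), TOUCH_COLS))
    stop("touch.csv columns differ from the documented format: ",
         paste(symdiff_chr(names(touch), TOUCH_COLS), collapse = ", "))
  for (cn in c("t", "x", "y")) touch[[cn]] <- as.numeric(touch[[cn]])
  touch$pointer_id <- as.integer(touch$pointer_id)
  imu <- utils::read.csv(file.path(path, man$imu_file %||% "imu.csv"))
  if (!setequal(names(imu), IMU_COLS))
    stop("imu.csv columns differ from the documented format: ",
         paste(symdiff_chr(names(imu), IMU_COLS), collapse = ", "))
  gameplay_session(subject_id = man$subject_id, group = man$group,
                   touch = touch[TOUCH_COLS], imu = imu[IMU_COLS],
                   duration = man$duration,
                   covariates = as.list(man$covariates))
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Write a session bundle to disk
#'
#' @param session a valid `gameplay_session`.
#' @param path target directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory ", path)
  man <- list(subject_id = session$subject_id, group = session$group,
              duration = session$duration, covariates = session$covariates,
              touch_file = "touch.csv", imu_file = "imu.csv")
  jsonlite::write_json(man, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(session$touch, file.path(path, "touch.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(session$imu, file.path(path, "imu.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the wide feature table
#'
#' One row per session: `subject_id`, `group`, then the 269 feature columns
#' in feature-registry order, regardless of the order features appear inside
#' the supplied vectors.
#'
#' @param vectors list of feature vectors from [extract_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(vectors, path) {
  df <- feature_table(vectors)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble feature vectors into a data frame
#'
#' @inheritParams write_feature_table
#' @return data frame with columns `subject_id`, `group`, then the registry
#'   feature columns.
#' @export
feature_table <- function(vectors) {
  reg_names <- feature_registry()$name
  if (length(vectors) == 0L) {
    df <- as.data.frame(c(list(subject_id = character(),
                               group = character()),
                          stats::setNames(rep(list(numeric()),
                                              length(reg_names)),
                                          reg_names)),
                        check.names = FALSE)
    return(df)
  }
  for (v in vectors) {
    if (!setequal(names(v$values), reg_names))
      stop("feature vector name set differs from the registry: ",
           paste(symdiff_chr(names(v$values), reg_names), collapse = ", "))
  }
  rows <- lapply(vectors, function(v)
    c(list(subject_id = v$subject_id, group = v$group),
      as.list(v$values[reg_names])))
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  rownames(df) <- NULL
  df
}
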