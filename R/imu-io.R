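# Data model and file I/O for shank IMU sessions.
#
# Axis convention (enforced by the synthetic generator, documented for real
# devices): sensor x = forward, y = lateral (the sagittal pitch axis, i.e.
# gyro channel 2 carries the pitch rate), z = up when standing. World frame:
# x forward, y lateral, z vertical (gravity = -z). Units are SI throughout
# (m/s^2, rad/s, s); converters exist only at the CSV boundary.

#' Sensor specification
#'
#' @param sampling_rate sampling frequency in Hz (the reference device records
#'   at 100 Hz).
#' @param accel_range accelerometer full-scale range in g units (reference
#'   device: 8).
#' @param gyro_range gyroscope full-scale range in deg/s (reference device:
#'   1000).
#' @param gravity gravitational acceleration in m/s^2.
#' @return object of class `sensor_spec`.
#' @export
sensor_spec <- function(sampling_rate = 100, accel_range = 8,
                        gyro_range = 1000, gravity = GRAVITY) {
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(accel_range, "accel_range", positive = TRUE)
  stopifnot_scalar(gyro_range, "gyro_range", positive = TRUE)
  stopifnot_scalar(gravity, "gravity", positive = TRUE)
  structure(
    list(
      sampling_rate = sampling_rate, accel_range = accel_range,
      gyro_range = gyro_range, gravity = gravity
    ),
    class = "sensor_spec"
  )
}

#' One leg's IMU time series
#'
#' @param side `"left"` or `"right"`.
#' @param time numeric vector of sample times (s), uniformly spaced.
#' @param accel n x 3 matrix of sensor-frame acceleration (m/s^2).
#' @param gyro n x 3 matrix of sensor-frame angular velocity (rad/s); column 2
#'   is the sagittal (pitch) channel by convention.
#' @param spec a [sensor_spec()].
#' @param validate check invariants (uniform sampling, finite values).
#' @return object of class `imu_series`.
#' @export
imu_series <- function(side, time, accel, gyro, spec = sensor_spec(),
                       validate = TRUE) {
  side <- match.arg(side, c("left", "right"))
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  x <- structure(
    list(side = side, time = as.numeric(time), accel = accel, gyro = gyro,
         spec = spec),
    class = "imu_series"
  )
  if (validate) {
    problems <- validate_imu_series(x)
    if (length(problems)) {
      stop("invalid imu_series: ", paste(problems, collapse = "; "),
           call. = FALSE)
    }
  }
  x
}

#' @export
format.imu_series <- function(x, ...) {
  sprintf(
    "<imu_series %s: %d samples @ %g Hz (%.2f s)>",
    x$side, length(x$time), x$spec$sampling_rate,
    if (length(x$time)) diff(range(x$time)) else 0
  )
}

#' @export
print.imu_series <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

validate_imu_series <- function(x, tol = 1e-6) {
  p <- character(0)
  n <- length(x$time)
  if (nrow(x$accel) != n || nrow(x$gyro) != n) {
    p <- c(p, sprintf("channel lengths differ (time %d, accel %d, gyro %d)",
                      n, nrow(x$accel), nrow(x$gyro)))
  }
  if (ncol(x$accel) != 3L || ncol(x$gyro) != 3L) {
    p <- c(p, "accel and gyro must have 3 columns")
  }
  if (anyNA(x$time) || any(!is.finite(x$time))) p <- c(p, "non-finite time values")
  if (anyNA(x$accel) || any(!is.finite(x$accel))) p <- c(p, "non-finite accel values")
  if (anyNA(x$gyro) || any(!is.finite(x$gyro))) p <- c(p, "non-finite gyro values")
  if (n >= 2L && !length(p)) {
    dt <- diff(x$time)
    step <- 1 / x$spec$sampling_rate
    bad <- which(abs(dt - step) > tol)
    if (any(dt <= 0)) {
      p <- c(p, sprintf("time not strictly increasing at row %d", which(dt <= 0)[1] + 1L))
    } else if (length(bad)) {
      p <- c(p, sprintf(
        "non-uniform sampling at row %d (step %.6g s, expected %.6g s)",
        bad[1] + 1L, dt[bad[1]], step
      ))
    }
  }
  p
}

#' A two-leg walking session
#'
#' @param participant_id character id.
#' @param group one of `"mild_pd"`, `"advanced_pd"`, `"healthy_older"`,
#'   `"healthy_young"` (or any label for ad hoc data).
#' @param left,right [imu_series()] objects for each leg.
#' @param spec shared [sensor_spec()].
#' @return object of class `walk_session`.
#' @export
walk_session <- function(participant_id, group, left, right,
                         spec = left$spec) {
  structure(
    list(participant_id = as.character(participant_id), group = group,
         left = left, right = right, spec = spec),
    class = "walk_session"
  )
}

#' @export
print.walk_session <- function(x, ...) {
  cat(sprintf("<walk_session %s [%s]>\n  %s\n  %s\n",
              x$participant_id, x$group, format(x$left), format(x$right)))
  invisible(x)
}

GROUP_LEVELS <- c("mild_pd", "advanced_pd", "healthy_older", "healthy_young")

# --- CSV dialect ------------------------------------------------------------
# One file per leg. Canonical layout:
#   # units: s,m/s2,rad/s
#   time_s,ax,ay,az,gx,gy,gz
# The units comment declares the time/accel/gyro units; "g" and "deg/s" are
# converted to SI on read. Values are written at 12 significant digits, which
# is lossless at the declared 1e-9 relative round-trip precision.

IMU_CSV_COLUMNS <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz")

#' Write an IMU series to CSV
#'
#' Canonical dialect: a `# units:` comment line, then the header
#' `time_s,ax,ay,az,gx,gy,gz`, SI units, 12 significant digits. Writing the
#' same series twice produces byte-identical files.
#'
#' @param series an [imu_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(series, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# units: s,m/s2,rad/s"), con)
  writeLines(paste(IMU_CSV_COLUMNS, collapse = ","), con)
  n <- length(series$time)
  if (n) {
    m <- cbind(series$time, series$accel, series$gyro)
    rows <- apply(m, 1L, function(r) paste(formatC(r, digits = 12, format = "g"),
                                           collapse = ","))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an IMU series from CSV
#'
#' Accepts the canonical dialect written by [write_imu_csv()]. If the
#' `# units:` comment declares `g` for acceleration or `deg/s` for angular
#' velocity, values are converted to SI. Sampling uniformity and sensor-range
#' invariants are enforced; the error message names the first offending row.
#'
#' @param path CSV file path.
#' @param spec a [sensor_spec()] describing the recording device.
#' @param side which leg the file belongs to.
#' @return an [imu_series()].
#' @export
read_imu_csv <- function(path, spec = sensor_spec(), side = "left") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 2L)
  units <- c("s", "m/s2", "rad/s")
  skip <- 0L
  if (length(lines) && startsWith(lines[1], "#")) {
    skip <- 1L
    m <- sub("^#\\s*units:\\s*", "", lines[1])
    declared <- trimws(strsplit(m, ",")[[1]])
    if (length(declared) == 3L) units <- declared
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE)
  missing_cols <- setdiff(IMU_CSV_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  accel <- as.matrix(df[, c("ax", "ay", "az")])
  gyro <- as.matrix(df[, c("gx", "gy", "gz")])
  if (identical(units[2], "g")) accel <- accel * spec$gravity
  if (units[3] %in% c("deg/s", "dps")) gyro <- gyro * pi / 180
  # sensor-range check (in device units)
  over_a <- which(abs(accel) > spec$accel_range * spec$gravity * (1 + 1e-9))
  if (length(over_a)) {
    stop(sprintf("acceleration exceeds +/-%g g range at row %d", spec$accel_range,
                 ((over_a[1] - 1L) %% nrow(accel)) + 1L), call. = FALSE)
  }
  over_g <- which(abs(gyro) > spec$gyro_range * pi / 180 * (1 + 1e-9))
  if (length(over_g)) {
    stop(sprintf("angular velocity exceeds +/-%g dps range at row %d", spec$gyro_range,
                 ((over_g[1] - 1L) %% nrow(gyro)) + 1L), call. = FALSE)
  }
  out <- imu_series(side, df$time_s, accel, gyro, spec, validate = FALSE)
  problems <- validate_imu_series(out)
  if (length(problems)) stop(problems[1], call. = FALSE)
  out
}

#' Validate a walking session
#'
#' Collects every invariant violation instead of raising, so callers can
#' report all problems at once. An empty character vector means the session is
#' valid. The left/right clock is assumed shared (no per-device
#' synchronization is attempted); a non-overlapping time support is reported.
#'
#' @param session a [walk_session()].
#' @return character vector of human-readable violations (empty if valid).
#' @export
validate_session <- function(session) {
  p <- character(0)
  for (side in c("left", "right")) {
    s <- session[[side]]
    sp <- validate_imu_series(s)
    if (length(sp)) p <- c(p, paste0(side, ": ", sp))
    if (length(s$time)) {
      lim_a <- s$spec$accel_range * s$spec$gravity
      if (max(abs(s$accel)) > lim_a) {
        p <- c(p, sprintf("%s: acceleration exceeds +/-%g g sensor range",
                          side, s$spec$accel_range))
      }
      lim_g <- s$spec$gyro_range * pi / 180
      if (max(abs(s$gyro)) > lim_g) {
        p <- c(p, sprintf("%s: angular velocity exceeds +/-%g dps sensor range",
                          side, s$spec$gyro_range))
      }
    }
  }
  if (!identical(session$left$spec$sampling_rate, session$right$spec$sampling_rate)) {
    p <- c(p, "left/right sampling rates differ")
  }
  if (length(session$left$time) && length(session$right$time)) {
    if (min(session$left$time) > max(session$right$time) ||
        min(session$right$time) > max(session$left$time)) {
      p <- c(p, "left/right time supports do not overlap")
    }
  }
  p
}
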