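# Quaternion handling and roll-angle extraction.
#
# The joint model consumes only the rotation of each sensor about its
# longitudinal ("roll") axis.  Orientation arrives as unit quaternions from
# the sensor firmware; the roll angle is the innermost angle of an intrinsic
# Tait-Bryan decomposition whose first axis is vertical, so the heading
# (magnetometer-derived yaw) never enters the result.

QUAT_NORM_TOL <- 1e-6

#' Construct a unit quaternion
#'
#' Scalar-first convention `(w, x, y, z)`. The norm must be 1 within `1e-6`;
#' quaternions within tolerance are renormalised exactly.
#'
#' @param w,x,y,z Numeric scalars (or equal-length vectors for a sample
#'   sequence) of the quaternion components.
#' @return A numeric matrix with one row per sample and columns
#'   `w, x, y, z`, of class `"quaternion"`.
#' @examples
#' quaternion(1, 0, 0, 0)                      # identity
#' quaternion(cos(pi / 12), sin(pi / 12), 0, 0) # 30 deg about x
#' @export
quaternion <- function(w, x, y, z) {
  q <- cbind(unname(w), unname(x), unname(y), unname(z))
  dimnames(q) <- list(NULL, c("w", "x", "y", "z"))
  storage.mode(q) <- "double"
  if (anyNA(q)) stop("quaternion components must be finite", call. = FALSE)
  n <- sqrt(rowSums(q^2))
  bad <- abs(n - 1) > QUAT_NORM_TOL
  if (any(bad)) {
    stop(sprintf(
      "non-unit quaternion: norm %.8f departs from 1 by more than %g",
      n[which(bad)[1]], QUAT_NORM_TOL
    ), call. = FALSE)
  }
  q <- q / n
  class(q) <- c("quaternion", "matrix")
  q
}

as_quaternion <- function(q) {
  if (inherits(q, "quaternion")) return(q)
  if (is.numeric(q) && is.null(dim(q)) && length(q) == 4L) {
    return(quaternion(q[1], q[2], q[3], q[4]))
  }
  if (is.matrix(q) && ncol(q) == 4L) {
    return(quaternion(q[, 1], q[, 2], q[, 3], q[, 4]))
  }
  stop("expected a quaternion: length-4 numeric or n x 4 matrix", call. = FALSE)
}

#' Hamilton product of two quaternions
#'
#' `quat_multiply(a, b)` composes rotations so that the rotation matrix of
#' the product is `R(a) %*% R(b)` (apply `b` first, then `a`). Either
#' argument may hold multiple rows; rows are recycled to the longer length.
#'
#' @param a,b Quaternions (see [quaternion()]).
#' @return The product quaternion(s).
#' @export
quat_multiply <- function(a, b) {
  a <- unclass(as_quaternion(a))
  b <- unclass(as_quaternion(b))
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  quaternion(
    w = a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    x = a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    y = a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    z = a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

#' Quaternion from intrinsic Tait-Bryan angles
#'
#' Builds the quaternion of the rotation `R_first(yaw) R_mid(pitch)
#' R_last(roll)` for the supported conventions. Under `"ZYX"` the roll axis
#' is x; under `"ZXY"` it is y. Angles are degrees.
#'
#' @param yaw,pitch,roll Angles in degrees (vectors recycled to a common
#'   length).
#' @param convention `"ZYX"` (default) or `"ZXY"`.
#' @return A `"quaternion"` matrix.
#' @export
quat_from_euler <- function(yaw = 0, pitch = 0, roll = 0, convention = c("ZYX", "ZXY")) {
  convention <- match.arg(convention)
  n <- max(length(yaw), length(pitch), length(roll))
  yaw <- rep_len(yaw, n) * pi / 180
  pitch <- rep_len(pitch, n) * pi / 180
  roll <- rep_len(roll, n) * pi / 180
  axis_quat <- function(angle, axis) {
    h <- angle / 2
    comp <- matrix(0, length(angle), 3L)
    comp[, axis] <- sin(h)
    quaternion(cos(h), comp[, 1], comp[, 2], comp[, 3])
  }
  if (convention == "ZYX") {
    quat_multiply(quat_multiply(axis_quat(yaw, 3L), axis_quat(pitch, 2L)),
                  axis_quat(roll, 1L))
  } else {
    quat_multiply(quat_multiply(axis_quat(yaw, 3L), axis_quat(pitch, 1L)),
                  axis_quat(roll, 2L))
  }
}

#' Roll angle about the sensor's longitudinal axis
#'
#' Extracts the innermost (roll) angle of the intrinsic Euler decomposition
#' of `q`. Both supported conventions start with a rotation about the
#' vertical (z) axis, so the result is invariant to any heading rotation
#' applied on top of `q` -- magnetometer-derived yaw never affects it.
#'
#' Near gimbal lock (pitch within `1e-6` degrees of +/-90) the roll/yaw
#' split is ill-conditioned; a warning is emitted and the two-argument
#' arctangent value is returned as-is.
#'
#' @param q A quaternion or n x 4 matrix of unit quaternions.
#' @param convention Euler sequence, `"ZYX"` (roll about x, default) or
#'   `"ZXY"` (roll about y).
#' @return Roll angle(s) in degrees, in (-180, 180].
#' @examples
#' roll_from_quaternion(quaternion(1, 0, 0, 0))            # 0
#' roll_from_quaternion(quat_from_euler(roll = 30))        # 30
#' roll_from_quaternion(quat_from_euler(yaw = 45, roll = 30)) # still 30
#' @export
roll_from_quaternion <- function(q, convention = c("ZYX", "ZXY")) {
  convention <- match.arg(convention)
  q <- unclass(as_quaternion(q))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # bottom row of the rotation matrix is unchanged by any premultiplied
  # z-axis (heading) rotation
  r31 <- 2 * (x * z - w * y)
  r32 <- 2 * (y * z + w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  if (convention == "ZYX") {
    sin_pitch <- -r31
    roll <- atan2(r32, r33)
  } else {
    sin_pitch <- r32
    roll <- atan2(-r31, r33)
  }
  pitch_deg <- asin(pmin(1, pmax(-1, sin_pitch))) * 180 / pi
  if (any(abs(abs(pitch_deg) - 90) < 1e-6)) {
    warning("pitch within 1e-6 deg of +/-90: roll/heading split is ill-conditioned",
            call. = FALSE)
  }
  deg <- unname(roll) * 180 / pi
  # map -180 exactly to +180 so the range is (-180, 180]
  deg[deg <= -180] <- deg[deg <= -180] + 360
  deg
}

#' Orientation time series for one sensor
#'
#' Holds either a quaternion sample sequence or pre-extracted roll angles
#' (degrees) for one of the three body-worn sensors, at a fixed sampling
#' rate. Time is 0-based: sample `i` is at `(i - 1) / rate_hz` seconds.
#'
#' @param sensor_id One of `"sacrum"`, `"thigh"`, `"shank"`.
#' @param quaternions Optional `"quaternion"` matrix of samples.
#' @param roll_deg Optional numeric vector of roll angles, degrees. Exactly
#'   one of `quaternions`/`roll_deg` must be given.
#' @param rate_hz Sampling rate in Hz (sensors in this protocol run at 60).
#' @param time_s Optional explicit timestamps; must be uniform at
#'   `1 / rate_hz` within `1e-9` s.
#' @return An `"orientation_series"` object.
#' @export
orientation_series <- function(sensor_id, quaternions = NULL, roll_deg = NULL,
                               rate_hz = 60, time_s = NULL) {
  sensor_id <- match.arg(sensor_id, c("sacrum", "thigh", "shank"))
  if (is.null(quaternions) == is.null(roll_deg)) {
    stop("exactly one of 'quaternions' and 'roll_deg' must be supplied",
         call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("rate_hz must be a positive scalar", call. = FALSE)
  }
  if (!is.null(quaternions)) {
    quaternions <- as_quaternion(quaternions)
    n <- nrow(quaternions)
  } else {
    roll_deg <- as.numeric(roll_deg)
    if (anyNA(roll_deg)) stop("roll_deg must be finite", call. = FALSE)
    n <- length(roll_deg)
  }
  if (n == 0L) stop("orientation series must contain at least one sample", call. = FALSE)
  if (!is.null(time_s)) {
    if (length(time_s) != n) stop("time_s length must match samples", call. = FALSE)
    if (n > 1L && max(abs(diff(time_s) - 1 / rate_hz)) >= 1e-9) {
      stop("timestamps are not uniform at 1/rate_hz within 1e-9 s", call. = FALSE)
    }
  }
  structure(
    list(sensor_id = sensor_id, quaternions = quaternions,
         roll_deg = roll_deg, rate_hz = rate_hz, n = n),
    class = "orientation_series"
  )
}

#' @export
print.orientation_series <- function(x, ...) {
  form <- if (is.null(x$quaternions)) "roll angles" else "quaternions"
  cat(sprintf("<orientation_series> sensor=%s  %d samples (%s) @ %g Hz (%.2f s)\n",
              x$sensor_id, x$n, form, x$rate_hz, x$n / x$rate_hz))
  invisible(x)
}

#' Continuous (unwrapped) roll-angle series for one sensor
#'
#' @param sensor_id Sensor label.
#' @param values_deg Unwrapped roll angles, degrees; successive differences
#'   must stay below 180 degrees in magnitude.
#' @param rate_hz Sampling rate, Hz.
#' @return A `"roll_series"` object.
#' @export
roll_series <- function(sensor_id, values_deg, rate_hz = 60) {
  values_deg <- as.numeric(values_deg)
  if (length(values_deg) == 0L) stop("empty roll series", call. = FALSE)
  if (anyNA(values_deg) || any(!is.finite(values_deg))) {
    stop("roll values must be finite", call. = FALSE)
  }
  if (length(values_deg) > 1L && any(abs(diff(values_deg)) >= 180)) {
    stop("roll series has a successive jump of 180 deg or more; unwrap first",
         call. = FALSE)
  }
  structure(list(sensor_id = sensor_id, values_deg = values_deg,
                 rate_hz = rate_hz, n = length(values_deg)),
            class = "roll_series")
}

#' @export
print.roll_series <- function(x, ...) {
  cat(sprintf("<roll_series> sensor=%s  %d samples @ %g Hz  range [%.2f, %.2f] deg\n",
              x$sensor_id, x$n, x$rate_hz, min(x$values_deg), max(x$values_deg)))
  invisible(x)
}

#' Unwrap a wrapped degree sequence
#'
#' Adds integer multiples of 360 so that successive differences are below
#' 180 degrees in magnitude; the first element is unchanged. Idempotent on
#' already-continuous input.
#'
#' @param values Numeric vector of angles, degrees.
#' @return Numeric vector, element-wise equal to `values` modulo 360.
#' @examples
#' unwrap_degrees(c(179, -179)) # 179 181
#' @export
unwrap_degrees <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("cannot unwrap an empty sequence", call. = FALSE)
  if (length(values) == 1L) return(values)
  d <- diff(values)
  wrapped <- ((d + 180) %% 360) - 180
  # keep exact +180 steps as +180 (the %% maps them to -180)
  wrapped[d == 180] <- 180
  values[1] + c(0, cumsum(wrapped))
}

#' Extract an unwrapped roll series from an orientation stream
#'
#' Per-sample roll extraction (see [roll_from_quaternion()]) followed by
#' unwrapping. A stream already holding roll angles is passed through the
#' unwrap step only.
#'
#' @param s An [orientation_series()].
#' @param convention Euler sequence passed to [roll_from_quaternion()].
#' @return A [roll_series()] of the same length and rate.
#' @export
extract_roll_series <- function(s, convention = c("ZYX", "ZXY")) {
  if (!inherits(s, "orientation_series")) {
    stop("'s' must be an orientation_series", call. = FALSE)
  }
  convention <- match.arg(convention)
  raw <- if (is.null(s$quaternions)) s$roll_deg
         else roll_from_quaternion(s$quaternions, convention)
  roll_series(s$sensor_id, unwrap_degrees(raw), s$rate_hz)
}

#' Read orientation streams from CSV
#'
#' Accepts the two stream dialects: `time_s, qw, qx, qy, qz` (quaternion)
#' or `time_s, roll_deg` (pre-extracted roll), optionally with a
#' `sensor_id` column holding several sensors in one file.
#'
#' @param path CSV file path (header row required, UTF-8).
#' @param rate_hz Sampling rate to validate the `time_s` column against.
#' @param sensor_id Sensor label used when the file has no `sensor_id`
#'   column.
#' @return A single [orientation_series()], or a named list of them when
#'   the file carries a `sensor_id` column.
#' @export
read_orientation_csv <- function(path, rate_hz = 60, sensor_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  quat_cols <- c("qw", "qx", "qy", "qz")
  has_quat <- all(quat_cols %in% names(df))
  has_roll <- "roll_deg" %in% names(df)
  if (!("time_s" %in% names(df)) || !(has_quat || has_roll)) {
    stop("CSV must have columns time_s + (qw,qx,qy,qz) or time_s + roll_deg",
         call. = FALSE)
  }
  build <- function(sub, id) {
    if (has_quat) {
      orientation_series(id, quaternions = quaternion(sub$qw, sub$qx, sub$qy, sub$qz),
                         rate_hz = rate_hz, time_s = sub$time_s)
    } else {
      orientation_series(id, roll_deg = sub$roll_deg, rate_hz = rate_hz,
                         time_s = sub$time_s)
    }
  }
  if ("sensor_id" %in% names(df)) {
    ids <- unique(df$sensor_id)
    out <- lapply(ids, function(id) build(df[df$sensor_id == id, , drop = FALSE], id))
    names(out) <- ids
    out
  } else {
    if (is.null(sensor_id)) {
      stop("file has no sensor_id column; supply sensor_id=", call. = FALSE)
    }
    build(df, sensor_id)
  }
}

#' Write orientation streams to CSV
#'
#' Inverse of [read_orientation_csv()]; several series are concatenated
#' with a `sensor_id` column.
#'
#' @param streams One [orientation_series()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_orientation_csv <- function(streams, path) {
  if (inherits(streams, "orientation_series")) streams <- list(streams)
  rows <- lapply(streams, function(s) {
    t <- (seq_len(s$n) - 1) / s$rate_hz
    if (!is.null(s$quaternions)) {
      q <- unclass(s$quaternions)
      data.frame(sensor_id = s$sensor_id, time_s = t,
                 qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
    } else {
      data.frame(sensor_id = s$sensor_id, time_s = t, roll_deg = s$roll_deg)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
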