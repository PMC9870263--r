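# Single-axis joint model: hip and knee flexion are differences of the
# segment roll angles (knee = thigh - shank, hip = sacrum - thigh), zeroed
# against the mean angle held during a 10-s anatomical standing trial.

#' Joint flexion-angle time series
#'
#' @param joint `"hip"` or `"knee"`.
#' @param source Where the angles came from: `"sensor"` (the three-IMU
#'   model), `"reference"` (camera-based motion capture), or `"truth"`
#'   (simulator ground truth).
#' @param values_deg Flexion angles, degrees, flexion positive.
#' @param rate_hz Sampling rate, Hz.
#' @param zeroed Has the static-trial offset already been subtracted?
#' @return A `"joint_angle_series"` object.
#' @export
joint_angle_series <- function(joint, source = "sensor", values_deg,
                               rate_hz = 60, zeroed = FALSE) {
  joint <- match.arg(joint, c("hip", "knee"))
  source <- match.arg(source, c("sensor", "reference", "truth"))
  values_deg <- as.numeric(values_deg)
  if (length(values_deg) == 0L) stop("joint-angle series must be non-empty", call. = FALSE)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("rate_hz must be a positive scalar", call. = FALSE)
  }
  structure(list(joint = joint, source = source, zeroed = isTRUE(zeroed),
                 values_deg = values_deg, rate_hz = rate_hz,
                 n = length(values_deg)),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %s/%s%s  %d samples @ %g Hz  range [%.2f, %.2f] deg\n",
              x$joint, x$source, if (x$zeroed) " (zeroed)" else "",
              x$n, x$rate_hz, min(x$values_deg), max(x$values_deg)))
  invisible(x)
}

check_same_grid <- function(a, b, what) {
  if (a$n != b$n) {
    stop(sprintf("%s: length mismatch (%d vs %d)", what, a$n, b$n), call. = FALSE)
  }
  if (a$rate_hz != b$rate_hz) {
    stop(sprintf("%s: rate mismatch (%g vs %g Hz)", what, a$rate_hz, b$rate_hz),
         call. = FALSE)
  }
}

#' Knee flexion from thigh and shank roll
#'
#' Element-wise `thigh - shank` of the two unwrapped roll series; any
#' common-mode rotation of the whole limb cancels.
#'
#' @param thigh,shank [roll_series()] objects on the same sampling grid.
#' @param sign_flip Negate the result (see [run_config()]'s per-joint sign
#'   flags).
#' @return An unzeroed sensor-source [joint_angle_series()] for the knee.
#' @export
knee_flexion <- function(thigh, shank, sign_flip = FALSE) {
  stopifnot(inherits(thigh, "roll_series"), inherits(shank, "roll_series"))
  check_same_grid(thigh, shank, "knee_flexion")
  v <- thigh$values_deg - shank$values_deg
  if (isTRUE(sign_flip)) v <- -v
  joint_angle_series("knee", "sensor", v, thigh$rate_hz, zeroed = FALSE)
}

#' Hip flexion from sacrum and thigh roll
#'
#' Element-wise `sacrum - thigh` of the two unwrapped roll series.
#'
#' @inheritParams knee_flexion
#' @param sacrum,thigh [roll_series()] objects on the same sampling grid.
#' @return An unzeroed sensor-source [joint_angle_series()] for the hip.
#' @export
hip_flexion <- function(sacrum, thigh, sign_flip = FALSE) {
  stopifnot(inherits(sacrum, "roll_series"), inherits(thigh, "roll_series"))
  check_same_grid(sacrum, thigh, "hip_flexion")
  v <- sacrum$values_deg - thigh$values_deg
  if (isTRUE(sign_flip)) v <- -v
  joint_angle_series("hip", "sensor", v, sacrum$rate_hz, zeroed = FALSE)
}

#' Static-trial calibration offsets
#'
#' @param hip_offset,knee_offset Mean joint angles (degrees) held during
#'   the standing trial.
#' @param trial_duration_s Length of the standing trial, seconds
#'   (protocol value 10).
#' @return A `"calibration_offsets"` object.
#' @export
calibration_offsets <- function(hip_offset, knee_offset, trial_duration_s = 10) {
  if (!is.finite(hip_offset) || !is.finite(knee_offset)) {
    stop("calibration offsets must be finite", call. = FALSE)
  }
  structure(list(hip_offset = hip_offset, knee_offset = knee_offset,
                 trial_duration_s = trial_duration_s),
            class = "calibration_offsets")
}

#' @export
print.calibration_offsets <- function(x, ...) {
  cat(sprintf("<calibration_offsets> hip %.3f deg, knee %.3f deg (%.0f-s standing trial)\n",
              x$hip_offset, x$knee_offset, x$trial_duration_s))
  invisible(x)
}

#' Compute zeroing offsets from a standing calibration trial
#'
#' The offset for each joint is the arithmetic mean of the joint angle over
#' the standing trial. `window` optionally restricts the average to a
#' central fraction of the trial to exclude postural sway while settling
#' at the trial edges.
#'
#' @param static_hip,static_knee [joint_angle_series()] recorded during the
#'   standing trial.
#' @param window `"full"` (default) or `"central"`.
#' @param central_fraction Fraction of the trial kept when
#'   `window = "central"` (centred).
#' @return A [calibration_offsets()] object.
#' @export
compute_offsets <- function(static_hip, static_knee, window = c("full", "central"),
                            central_fraction = 0.8) {
  stopifnot(inherits(static_hip, "joint_angle_series"),
            inherits(static_knee, "joint_angle_series"))
  window <- match.arg(window)
  trial_mean <- function(s) {
    v <- s$values_deg
    if (window == "central") {
      keep <- max(1L, floor(length(v) * central_fraction))
      lo <- floor((length(v) - keep) / 2) + 1L
      v <- v[lo:(lo + keep - 1L)]
    }
    mean(v)
  }
  calibration_offsets(trial_mean(static_hip), trial_mean(static_knee),
                      trial_duration_s = static_hip$n / static_hip$rate_hz)
}

#' Zero a joint-angle series against the static-trial offsets
#'
#' Subtracts the joint's standing-trial mean. Applies to sensor-derived
#' series (always zeroed before validation) and to reference series (to
#' form the zeroed reference variant). Zeroing an already-zeroed series is
#' an error.
#'
#' @param series A [joint_angle_series()] with `zeroed = FALSE`.
#' @param offsets A [calibration_offsets()] object.
#' @return The series with the offset removed and `zeroed = TRUE`.
#' @export
apply_zeroing <- function(series, offsets) {
  stopifnot(inherits(series, "joint_angle_series"),
            inherits(offsets, "calibration_offsets"))
  if (series$zeroed) {
    stop("series is already zeroed; refusing to subtract the offset twice",
         call. = FALSE)
  }
  off <- if (series$joint == "hip") offsets$hip_offset else offsets$knee_offset
  joint_angle_series(series$joint, series$source, series$values_deg - off,
                     series$rate_hz, zeroed = TRUE)
}

#' Write joint-angle series to CSV
#'
#' Columns `time_s, joint, source, zeroed, angle_deg`; several series are
#' concatenated.
#'
#' @param series_list One [joint_angle_series()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_joint_angles_csv <- function(series_list, path) {
  if (inherits(series_list, "joint_angle_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    data.frame(time_s = (seq_len(s$n) - 1) / s$rate_hz, joint = s$joint,
               source = s$source, zeroed = s$zeroed, angle_deg = s$values_deg)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read joint-angle series from CSV
#'
#' Inverse of [write_joint_angles_csv()]. Each distinct
#' (joint, source, zeroed) combination becomes one series.
#'
#' @param path CSV path.
#' @param rate_hz Sampling rate used to rebuild the series.
#' @return A list of [joint_angle_series()], named `joint.source`.
#' @export
read_joint_angles_csv <- function(path, rate_hz = 60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "joint", "source", "zeroed", "angle_deg")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  key <- interaction(df$joint, df$source, df$zeroed, drop = TRUE)
  out <- lapply(split(df, key), function(sub) {
    sub <- sub[order(sub$time_s), , drop = FALSE]
    joint_angle_series(sub$joint[1], sub$source[1], sub$angle_deg,
                       rate_hz = rate_hz, zeroed = as.logical(sub$zeroed[1]))
  })
  names(out) <- vapply(out, function(s) {
    paste(s$joint, s$source, if (s$zeroed) "zeroed" else "raw", sep = ".")
  }, "")
  out
}
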