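# Synthetic gait-session generator.
#
# Emulates the study protocol end-to-end with no recorded data: per
# participant a 10-s standing calibration trial plus two 1-minute walking
# trials (timepoints T1 and T2, before and after a treadmill session),
# from which the second 20-s period is analyzed.  Ground-truth hip/knee
# flexion waveforms are periodic harmonic series with cycle-duration
# jitter; segment rolls are solved so the single-axis joint model inverts
# them exactly; sensor corruption adds mounting offsets, slow drift,
# white noise and a soft-tissue artifact coupled to joint excursion, and
# the camera-like reference stream gets independent small noise plus a
# clock offset (integer-sample lag) relative to the sensors.

#' Gait waveform profile
#'
#' Hip and knee flexion over the gait cycle are modelled as harmonic
#' series: `baseline + sum_k A_k * cos(k * phase + p_k)` with `phase` in
#' radians over one cycle. Defaults give normative-looking sagittal
#' waveforms: hip swinging 30 to -10 degrees across the cycle, knee with a
#' small stance wave and a swing peak near 60 degrees about 70% through
#' the cycle. These are synthetic shapes, not fits to any recording.
#'
#' @param cycle_duration_s Mean gait-cycle duration, seconds.
#' @param hip_harmonics,knee_harmonics List of `c(amplitude_deg,
#'   phase_rad)` per harmonic (element k is harmonic k).
#' @param hip_baseline,knee_baseline Baseline angles, degrees.
#' @param cycle_jitter_cv Coefficient of variation of cycle duration
#'   (stride-time variability).
#' @param stand_hip_deg,stand_knee_deg Joint angles held during the
#'   standing calibration pose, degrees (small residual flexion).
#' @return A `"gait_profile"` object. Construction fails if the waveforms
#'   leave the physiological envelope (knee in \[-5, 90\], hip in
#'   \[-30, 60\] degrees).
#' @export
gait_profile <- function(cycle_duration_s = 1.1,
                         hip_harmonics = list(c(20, 0)),
                         knee_harmonics = list(c(22, 1.8832), c(13, 3.7664)),
                         hip_baseline = 10, knee_baseline = 25,
                         cycle_jitter_cv = 0.03,
                         stand_hip_deg = 2, stand_knee_deg = 4) {
  p <- structure(list(cycle_duration_s = cycle_duration_s,
                      hip_harmonics = hip_harmonics,
                      knee_harmonics = knee_harmonics,
                      hip_baseline = hip_baseline, knee_baseline = knee_baseline,
                      cycle_jitter_cv = cycle_jitter_cv,
                      stand_hip_deg = stand_hip_deg,
                      stand_knee_deg = stand_knee_deg),
                 class = "gait_profile")
  if (cycle_duration_s <= 0) stop("cycle_duration_s must be positive", call. = FALSE)
  if (cycle_jitter_cv < 0) stop("cycle_jitter_cv must be >= 0", call. = FALSE)
  phase <- seq(0, 2 * pi, length.out = 721)
  hip <- eval_harmonics(phase, hip_harmonics, hip_baseline)
  knee <- eval_harmonics(phase, knee_harmonics, knee_baseline)
  if (min(knee) < -5 || max(knee) > 90) {
    stop(sprintf("knee waveform [%.1f, %.1f] leaves the physiological envelope [-5, 90] deg",
                 min(knee), max(knee)), call. = FALSE)
  }
  if (min(hip) < -30 || max(hip) > 60) {
    stop(sprintf("hip waveform [%.1f, %.1f] leaves the physiological envelope [-30, 60] deg",
                 min(hip), max(hip)), call. = FALSE)
  }
  p
}

eval_harmonics <- function(phase, harmonics, baseline) {
  v <- rep(baseline, length(phase))
  for (k in seq_along(harmonics)) {
    h <- harmonics[[k]]
    v <- v + h[1] * cos(k * phase + h[2])
  }
  v
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf("<gait_profile> cycle %.2f s (cv %.2f), hip base %g deg (%d harm.), knee base %g deg (%d harm.)\n",
              x$cycle_duration_s, x$cycle_jitter_cv, x$hip_baseline,
              length(x$hip_harmonics), x$knee_baseline, length(x$knee_harmonics)))
  invisible(x)
}

#' Sensor corruption model
#'
#' Additive error terms applied to each sensor's true segment roll:
#' a constant mounting offset (mis-seating of the case on the segment), a
#' linear drift, white measurement noise, and a soft-tissue artifact
#' proportional to the low-pass-filtered excursion of the adjacent joint
#' (muscle contraction moving the case relative to the bone) applied to
#' the muscle-mounted thigh and shank sensors only. `t2_offset_shift_deg`
#' is an extra constant offset present only at the second timepoint,
#' emulating attachment-tape degradation over the treadmill session.
#' A constant per-sensor heading is applied when the rolls are packed into
#' quaternions; roll extraction must be insensitive to it.
#'
#' @param static_offset_deg Named length-3 numeric (sacrum, thigh, shank)
#'   or scalar, degrees.
#' @param white_sd_deg White-noise standard deviation, degrees.
#' @param drift_deg_per_min Linear drift rate, degrees per minute (clock
#'   starts at each trial's first sample).
#' @param soft_tissue_gain Unitless gain on the adjacent joint's
#'   mean-removed, low-pass-filtered excursion (thigh uses the hip,
#'   shank the knee).
#' @param t2_offset_shift_deg Extra per-sensor offset at timepoint T2,
#'   degrees (length 3 or scalar).
#' @param heading_deg Constant per-sensor heading (yaw), degrees.
#' @param soft_tissue_cutoff_hz Low-pass corner of the artifact, Hz.
#' @param seed Seed for the white-noise draws.
#' @return A `"sensor_noise_model"` object.
#' @export
sensor_noise_model <- function(static_offset_deg = c(sacrum = 0, thigh = 0, shank = 0),
                               white_sd_deg = 0.3, drift_deg_per_min = 0.2,
                               soft_tissue_gain = 0.05,
                               t2_offset_shift_deg = c(sacrum = 0, thigh = 0, shank = 0),
                               heading_deg = c(sacrum = 0, thigh = 0, shank = 0),
                               soft_tissue_cutoff_hz = 4, seed = 1L) {
  expand3 <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, 3)
    if (length(x) != 3L) stop(what, " must have length 1 or 3", call. = FALSE)
    names(x) <- c("sacrum", "thigh", "shank")
    x
  }
  if (white_sd_deg < 0 || drift_deg_per_min < 0 || soft_tissue_gain < 0) {
    stop("noise magnitudes must be >= 0", call. = FALSE)
  }
  structure(list(static_offset_deg = expand3(static_offset_deg, "static_offset_deg"),
                 white_sd_deg = white_sd_deg,
                 drift_deg_per_min = drift_deg_per_min,
                 soft_tissue_gain = soft_tissue_gain,
                 t2_offset_shift_deg = expand3(t2_offset_shift_deg, "t2_offset_shift_deg"),
                 heading_deg = expand3(heading_deg, "heading_deg"),
                 soft_tissue_cutoff_hz = soft_tissue_cutoff_hz,
                 seed = as.integer(seed)),
            class = "sensor_noise_model")
}

#' @export
print.sensor_noise_model <- function(x, ...) {
  cat(sprintf("<sensor_noise_model> offsets [%s] deg, white %.2f deg, drift %.2f deg/min, soft-tissue gain %.3f, T2 shift [%s] deg\n",
              paste(sprintf("%.1f", x$static_offset_deg), collapse = ", "),
              x$white_sd_deg, x$drift_deg_per_min, x$soft_tissue_gain,
              paste(sprintf("%.1f", x$t2_offset_shift_deg), collapse = ", ")))
  invisible(x)
}

# deterministic sub-seed expansion (kept below 2^31)
sub_seed <- function(seed, participant, stream) {
  ((as.double(seed) + 104729 * participant + 7919 * stream) %% 2147483587) + 1
}

#' Generate ground-truth hip and knee flexion
#'
#' Evaluates the profile's harmonic waveforms over a phase track whose
#' cycle durations are jittered (normal, truncated at 3 sd, cv
#' `cycle_jitter_cv`), giving stride-to-stride variability.
#'
#' @param profile A [gait_profile()].
#' @param duration_s Trial duration, seconds.
#' @param rate_hz Sampling rate, Hz.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `hip` and `knee` truth-source [joint_angle_series()].
#' @export
generate_truth <- function(profile, duration_s, rate_hz = 60, seed = 1L) {
  stopifnot(inherits(profile, "gait_profile"))
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  set.seed(as.integer(seed))
  n_cycles <- ceiling(duration_s / profile$cycle_duration_s) + 2L
  z <- pmin(3, pmax(-3, stats::rnorm(n_cycles)))
  durs <- profile$cycle_duration_s * (1 + profile$cycle_jitter_cv * z)
  durs <- pmax(durs, 0.2 * profile$cycle_duration_s)
  while (sum(durs) < duration_s) {
    z1 <- pmin(3, pmax(-3, stats::rnorm(1)))
    durs <- c(durs, profile$cycle_duration_s * (1 + profile$cycle_jitter_cv * z1))
  }
  bounds <- c(0, cumsum(durs))
  cyc <- findInterval(t, bounds, rightmost.closed = FALSE)
  frac <- (t - bounds[cyc]) / durs[cyc]
  phase <- 2 * pi * (cyc - 1 + frac)
  list(hip = joint_angle_series("hip", "truth",
                                eval_harmonics(phase, profile$hip_harmonics,
                                               profile$hip_baseline), rate_hz),
       knee = joint_angle_series("knee", "truth",
                                 eval_harmonics(phase, profile$knee_harmonics,
                                                profile$knee_baseline), rate_hz))
}

#' Segment rolls realizing given joint trajectories
#'
#' Solves the single-axis model for the three segment rolls so that
#' `hip = sacrum - thigh` and `knee = thigh - shank` hold exactly:
#' `sacrum = pelvis_motion`, `thigh = sacrum - hip`,
#' `shank = thigh - knee`.
#'
#' @param truth_hip,truth_knee [joint_angle_series()] of equal length.
#' @param pelvis_motion Numeric vector of sacrum roll, degrees (recycled;
#'   default 0). Adding any common-mode term here leaves the recovered
#'   joints unchanged.
#' @return Named list of three [roll_series()]: `sacrum`, `thigh`, `shank`.
#' @export
truth_to_segment_rolls <- function(truth_hip, truth_knee, pelvis_motion = 0) {
  stopifnot(inherits(truth_hip, "joint_angle_series"),
            inherits(truth_knee, "joint_angle_series"))
  if (truth_hip$n != truth_knee$n) stop("hip/knee length mismatch", call. = FALSE)
  sacrum <- rep_len(as.numeric(pelvis_motion), truth_hip$n)
  thigh <- sacrum - truth_hip$values_deg
  shank <- thigh - truth_knee$values_deg
  r <- truth_hip$rate_hz
  list(sacrum = roll_series("sacrum", sacrum, r),
       thigh = roll_series("thigh", thigh, r),
       shank = roll_series("shank", shank, r))
}

soft_tissue_artifact <- function(excursion, gain, cutoff_hz, rate_hz) {
  if (gain == 0) return(rep(0, length(excursion)))
  x <- excursion - mean(excursion)
  w <- min(0.99, cutoff_hz / (rate_hz / 2))
  if (length(x) > 12L) {
    bf <- signal::butter(2, w, type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  gain * x
}

#' Corrupt segment rolls into noisy sensor orientation streams
#'
#' Applies the [sensor_noise_model()] terms to each segment roll and packs
#' the result into unit quaternions (roll about the longitudinal axis plus
#' the model's constant per-sensor heading). The soft-tissue artifact is
#' driven by the joint excursions implied by the input rolls themselves
#' and is added to the thigh and shank sensors only.
#'
#' @param rolls Named list of [roll_series()] (`sacrum`, `thigh`, `shank`).
#' @param noise A [sensor_noise_model()].
#' @param timepoint `"T1"` or `"T2"`; the T2 offset shift is applied only
#'   at `"T2"`.
#' @param convention Euler convention for the quaternion packing.
#' @return Named list of three quaternion [orientation_series()].
#' @export
corrupt_rolls <- function(rolls, noise, timepoint = c("T1", "T2"),
                          convention = c("ZYX", "ZXY")) {
  timepoint <- match.arg(timepoint)
  convention <- match.arg(convention)
  stopifnot(inherits(noise, "sensor_noise_model"))
  ids <- c("sacrum", "thigh", "shank")
  if (!all(ids %in% names(rolls))) {
    stop("rolls must be a named list with sacrum, thigh, shank", call. = FALSE)
  }
  rate <- rolls$sacrum$rate_hz
  n <- rolls$sacrum$n
  t_min <- (seq_len(n) - 1) / rate / 60
  hip_exc <- rolls$sacrum$values_deg - rolls$thigh$values_deg
  knee_exc <- rolls$thigh$values_deg - rolls$shank$values_deg
  artifact <- list(
    sacrum = rep(0, n),
    thigh = soft_tissue_artifact(hip_exc, noise$soft_tissue_gain,
                                 noise$soft_tissue_cutoff_hz, rate),
    shank = soft_tissue_artifact(knee_exc, noise$soft_tissue_gain,
                                 noise$soft_tissue_cutoff_hz, rate)
  )
  set.seed(noise$seed)
  out <- lapply(ids, function(id) {
    v <- rolls[[id]]$values_deg +
      noise$static_offset_deg[[id]] +
      (if (timepoint == "T2") noise$t2_offset_shift_deg[[id]] else 0) +
      noise$drift_deg_per_min * t_min +
      artifact[[id]] +
      (if (noise$white_sd_deg > 0) stats::rnorm(n, 0, noise$white_sd_deg) else 0)
    q <- quat_from_euler(yaw = noise$heading_deg[[id]], pitch = 0, roll = v,
                         convention = convention)
    orientation_series(id, quaternions = q, rate_hz = rate)
  })
  names(out) <- ids
  out
}

#' Treadmill session schedule
#'
#' The walking protocol between the two measurement timepoints: bouts of
#' treadmill walking alternated with seated rest (rests between bouts
#' only). The default four 8-minute bouts with 3-minute rests total
#' 41 minutes.
#'
#' @param n_bouts Number of walking bouts.
#' @param bout_duration_min Bout length, minutes.
#' @param rest_duration_min Rest length, minutes.
#' @return A `"session_schedule"` data frame of phases (`phase`,
#'   `start_min`, `end_min`) with attribute `total_min`.
#' @export
session_schedule <- function(n_bouts = 4, bout_duration_min = 8,
                             rest_duration_min = 3) {
  stopifnot(n_bouts >= 1)
  phases <- character(0); durs <- numeric(0)
  for (i in seq_len(n_bouts)) {
    phases <- c(phases, sprintf("walk_%d", i)); durs <- c(durs, bout_duration_min)
    if (i < n_bouts) {
      phases <- c(phases, sprintf("rest_%d", i)); durs <- c(durs, rest_duration_min)
    }
  }
  ends <- cumsum(durs)
  out <- data.frame(phase = phases, start_min = ends - durs, end_min = ends)
  attr(out, "total_min") <- sum(durs)
  class(out) <- c("session_schedule", "data.frame")
  out
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> %d phases, total %g min\n",
              nrow(x), attr(x, "total_min")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Default cohort parameter ranges
#'
#' Per-participant simulator parameters are drawn uniformly from these
#' ranges. The defaults reflect a healthy cohort walking at preferred
#' speed with carefully taped sensors: modest mounting offsets, sub-degree
#' white noise, slow drift, a small soft-tissue coupling, and a
#' tape-degradation offset at T2 concentrated on the shank (largest on the
#' segment wrapped over the calf); the camera-like reference has 0.3-deg
#' noise and a small constant offset.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
cohort_ranges <- function() {
  list(cycle = c(1.0, 1.2), amp_scale = c(0.9, 1.1),
       hip_baseline = c(8, 12), knee_baseline = c(23, 27),
       jitter_cv = c(0.02, 0.04),
       stand_hip = c(0, 4), stand_knee = c(1, 6),
       pelvis_amp = c(1, 3),
       static_offset = c(-3, 3), white_sd = c(0.2, 0.5),
       drift = c(0, 0.5), soft_tissue_gain = c(0.02, 0.08),
       t2_shift_thigh = c(0.2, 1.2), t2_shift_shank = c(-3, -1),
       heading = c(-180, 180),
       ref_sd = c(0.25, 0.35), ref_offset = c(-1, 1),
       lag = c(-120, 120))
}

#' Noise-free cohort parameter ranges
#'
#' All noise, offset, lag and jitter ranges collapsed to zero; used for
#' exact round-trip checks of the pipeline.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
noise_free_ranges <- function() {
  r <- cohort_ranges()
  for (k in c("static_offset", "white_sd", "drift", "soft_tissue_gain",
              "t2_shift_thigh", "t2_shift_shank", "heading",
              "ref_sd", "ref_offset", "lag", "stand_hip", "stand_knee",
              "jitter_cv")) {
    r[[k]] <- c(0, 0)
  }
  r
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Simulate a cohort of gait sessions
#'
#' For each participant: draws a gait profile and noise model from
#' `ranges`, generates a standing calibration trial and two walking trials
#' (timepoints T1 and T2), corrupts the sensor streams, and produces
#' camera-like reference joint angles with independent noise, a constant
#' offset and an integer-sample clock lag relative to the sensor streams.
#' All per-participant parameters are recorded in the returned manifest.
#'
#' @param n_participants Cohort size (study cohort: 20).
#' @param trial_duration_s Walking-trial length, seconds (protocol: 60).
#' @param rate_hz Sampling rate, Hz (protocol: 60).
#' @param calibration_s Standing-trial length, seconds (protocol: 10).
#' @param ranges Parameter ranges, see [cohort_ranges()].
#' @param seed Master seed; expanded deterministically into
#'   per-participant, per-trial sub-seeds.
#' @return A `"sim_cohort"` object: list with `participants` (each holding
#'   `calibration`, `T1`, `T2` sessions and `params`), plus `rate_hz` and
#'   `manifest`.
#' @export
simulate_cohort <- function(n_participants = 20, trial_duration_s = 60,
                            rate_hz = 60, calibration_s = 10,
                            ranges = cohort_ranges(), seed = 1L) {
  stopifnot(n_participants >= 1)
  participants <- list()
  for (p in seq_len(n_participants)) {
    set.seed(sub_seed(seed, p, 0))
    amp <- runif1(ranges$amp_scale)
    prof <- gait_profile(
      cycle_duration_s = runif1(ranges$cycle),
      hip_harmonics = list(c(20 * amp, 0)),
      knee_harmonics = list(c(22 * amp, 1.8832), c(13 * amp, 3.7664)),
      hip_baseline = runif1(ranges$hip_baseline),
      knee_baseline = runif1(ranges$knee_baseline),
      cycle_jitter_cv = runif1(ranges$jitter_cv),
      stand_hip_deg = runif1(ranges$stand_hip),
      stand_knee_deg = runif1(ranges$stand_knee))
    noise <- sensor_noise_model(
      static_offset_deg = stats::runif(3, ranges$static_offset[1], ranges$static_offset[2]),
      white_sd_deg = runif1(ranges$white_sd),
      drift_deg_per_min = runif1(ranges$drift),
      soft_tissue_gain = runif1(ranges$soft_tissue_gain),
      t2_offset_shift_deg = c(0, runif1(ranges$t2_shift_thigh),
                              runif1(ranges$t2_shift_shank)),
      heading_deg = stats::runif(3, ranges$heading[1], ranges$heading[2]),
      seed = sub_seed(seed, p, 9))
    pelvis_amp <- runif1(ranges$pelvis_amp)
    ref_sd <- runif1(ranges$ref_sd)
    ref_offset <- stats::runif(2, ranges$ref_offset[1], ranges$ref_offset[2])
    lags <- as.integer(round(stats::runif(2, ranges$lag[1], ranges$lag[2])))
    id <- sprintf("P%02d", p)
    calibration <- simulate_calibration(id, prof, noise, calibration_s, rate_hz,
                                        ref_sd, ref_offset,
                                        seed = sub_seed(seed, p, 3))
    sessions <- lapply(1:2, function(tp) {
      simulate_walking_trial(id, prof, noise, trial_duration_s, rate_hz,
                             pelvis_amp, ref_sd, ref_offset,
                             lag = lags[tp],
                             timepoint = c("T1", "T2")[tp],
                             seed = sub_seed(seed, p, tp))
    })
    participants[[id]] <- list(
      id = id, calibration = calibration,
      T1 = sessions[[1]], T2 = sessions[[2]],
      params = list(profile = prof, noise = noise, pelvis_amp = pelvis_amp,
                    ref_sd = ref_sd, ref_offset = ref_offset,
                    lag_T1 = lags[1], lag_T2 = lags[2]))
  }
  manifest <- lapply(participants, function(pt) {
    list(id = pt$id,
         cycle_duration_s = pt$params$profile$cycle_duration_s,
         hip_baseline = pt$params$profile$hip_baseline,
         knee_baseline = pt$params$profile$knee_baseline,
         stand_hip_deg = pt$params$profile$stand_hip_deg,
         stand_knee_deg = pt$params$profile$stand_knee_deg,
         static_offset_deg = unname(pt$params$noise$static_offset_deg),
         white_sd_deg = pt$params$noise$white_sd_deg,
         drift_deg_per_min = pt$params$noise$drift_deg_per_min,
         soft_tissue_gain = pt$params$noise$soft_tissue_gain,
         t2_offset_shift_deg = unname(pt$params$noise$t2_offset_shift_deg),
         ref_sd = pt$params$ref_sd, ref_offset = unname(pt$params$ref_offset),
         lag_T1 = pt$params$lag_T1, lag_T2 = pt$params$lag_T2)
  })
  structure(list(participants = participants, rate_hz = rate_hz,
                 trial_duration_s = trial_duration_s,
                 calibration_s = calibration_s, seed = seed,
                 manifest = manifest),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d participants, %g-s trials + %g-s calibration @ %g Hz (seed %s)\n",
              length(x$participants), x$trial_duration_s, x$calibration_s,
              x$rate_hz, format(x$seed)))
  invisible(x)
}

# standing trial: constant pose, no pelvis motion, no lag
simulate_calibration <- function(id, profile, noise, duration_s, rate_hz,
                                 ref_sd, ref_offset, seed) {
  n <- round(duration_s * rate_hz)
  hip <- joint_angle_series("hip", "truth", rep(profile$stand_hip_deg, n), rate_hz)
  knee <- joint_angle_series("knee", "truth", rep(profile$stand_knee_deg, n), rate_hz)
  rolls <- truth_to_segment_rolls(hip, knee, pelvis_motion = 0)
  noise_cal <- noise
  noise_cal$seed <- as.integer(seed)
  sensors <- corrupt_rolls(rolls, noise_cal, timepoint = "T1")
  set.seed(as.integer(seed) + 1L)
  ref_hip <- joint_angle_series("hip", "reference",
                                hip$values_deg + ref_offset[1] +
                                  stats::rnorm(n, 0, ref_sd), rate_hz)
  ref_knee <- joint_angle_series("knee", "reference",
                                 knee$values_deg + ref_offset[2] +
                                   stats::rnorm(n, 0, ref_sd), rate_hz)
  list(participant_id = id, truth_hip = hip, truth_knee = knee,
       sensors = sensors, reference_hip = ref_hip, reference_knee = ref_knee)
}

# walking trial: truth generated with margin so the reference window can be
# shifted by the injected clock lag without running out of samples
simulate_walking_trial <- function(id, profile, noise, duration_s, rate_hz,
                                   pelvis_amp, ref_sd, ref_offset, lag,
                                   timepoint, seed) {
  n <- round(duration_s * rate_hz)
  margin <- max(1L, abs(lag))
  truth_full <- generate_truth(profile, (n + 2 * margin) / rate_hz, rate_hz,
                               seed = seed)
  win <- (margin + 1):(margin + n)
  hip <- joint_angle_series("hip", "truth", truth_full$hip$values_deg[win], rate_hz)
  knee <- joint_angle_series("knee", "truth", truth_full$knee$values_deg[win], rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  pelvis <- pelvis_amp * sin(2 * pi * t / profile$cycle_duration_s)
  rolls <- truth_to_segment_rolls(hip, knee, pelvis_motion = pelvis)
  noise_tp <- noise
  noise_tp$seed <- as.integer(sub_seed(noise$seed, 1, match(timepoint, c("T1", "T2"))))
  sensors <- corrupt_rolls(rolls, noise_tp, timepoint = timepoint)
  # reference stream: same truth, window shifted by +lag samples, so the
  # sensor stream lags the reference by `lag` in the cross-correlation sense
  refwin <- win + lag
  set.seed(as.integer(seed) + 2L)
  ref_hip <- joint_angle_series("hip", "reference",
                                truth_full$hip$values_deg[refwin] + ref_offset[1] +
                                  stats::rnorm(n, 0, ref_sd), rate_hz)
  ref_knee <- joint_angle_series("knee", "reference",
                                 truth_full$knee$values_deg[refwin] + ref_offset[2] +
                                   stats::rnorm(n, 0, ref_sd), rate_hz)
  structure(list(participant_id = id, timepoint = timepoint,
                 truth_hip = hip, truth_knee = knee, sensors = sensors,
                 reference_hip = ref_hip, reference_knee = ref_knee,
                 injected_lag_samples = as.integer(lag)),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %s %s: %d samples, injected lag %+d samples\n",
              x$participant_id, x$timepoint, x$truth_hip$n,
              x$injected_lag_samples))
  invisible(x)
}

#' Write a simulated cohort to CSV files plus a JSON manifest
#'
#' One sensor-stream CSV and one reference joint-angle CSV per
#' participant-trial (calibration, T1, T2), in the dialects the readers
#' consume, plus `manifest.json` holding every ground-truth parameter.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (pt in cohort$participants) {
    base <- file.path(dir, pt$id)
    write_orientation_csv(pt$calibration$sensors,
                          paste0(base, "_calibration_sensors.csv"))
    write_joint_angles_csv(list(pt$calibration$reference_hip,
                                pt$calibration$reference_knee),
                           paste0(base, "_calibration_reference.csv"))
    for (tp in c("T1", "T2")) {
      s <- pt[[tp]]
      write_orientation_csv(s$sensors, paste0(base, "_", tp, "_sensors.csv"))
      write_joint_angles_csv(list(s$reference_hip, s$reference_knee),
                             paste0(base, "_", tp, "_reference.csv"))
    }
  }
  jsonlite::write_json(
    list(seed = cohort$seed, rate_hz = cohort$rate_hz,
         trial_duration_s = cohort$trial_duration_s,
         calibration_s = cohort$calibration_s,
         participants = unname(cohort$manifest)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = 10)
  invisible(dir)
}
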