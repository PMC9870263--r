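# Synthetic gait generator: waveforms, inversion, corruption, cohort.

test_that("generate_truth honours baseline, amplitude and determinism", {
  flat <- gait_profile(hip_harmonics = list(c(0, 0)),
                       knee_harmonics = list(c(0, 0)),
                       hip_baseline = 10, knee_baseline = 25,
                       cycle_jitter_cv = 0)
  tr <- generate_truth(flat, duration_s = 5, rate_hz = 60, seed = 1)
  expect_equal(tr$hip$values_deg, rep(10, 300))
  expect_equal(tr$knee$values_deg, rep(25, 300))
  # single harmonic of amplitude A spans 2A around the baseline
  one <- gait_profile(hip_harmonics = list(c(15, 0)),
                      knee_harmonics = list(c(10, 0)),
                      hip_baseline = 5, knee_baseline = 30,
                      cycle_jitter_cv = 0)
  tr1 <- generate_truth(one, duration_s = 20, rate_hz = 60, seed = 1)
  expect_equal(max(tr1$hip$values_deg), 20, tolerance = 1e-6)
  expect_equal(min(tr1$hip$values_deg), -10, tolerance = 0.01)
  # identical seeds reproduce bitwise; different seeds jitter differently
  jit <- gait_profile()
  a <- generate_truth(jit, 10, 60, seed = 7)
  b <- generate_truth(jit, 10, 60, seed = 7)
  c <- generate_truth(jit, 10, 60, seed = 8)
  expect_identical(a$knee$values_deg, b$knee$values_deg)
  expect_false(identical(a$knee$values_deg, c$knee$values_deg))
})

test_that("profiles outside the physiological envelope are rejected", {
  expect_error(gait_profile(knee_harmonics = list(c(80, 0))), "knee waveform")
  expect_error(gait_profile(hip_harmonics = list(c(60, 0))), "hip waveform")
  expect_s3_class(gait_profile(), "gait_profile")
})

test_that("segment rolls invert the joint model exactly", {
  n <- 50
  hip <- joint_angle_series("hip", "truth", rep(30, n))
  knee <- joint_angle_series("knee", "truth", rep(20, n))
  rolls <- truth_to_segment_rolls(hip, knee, pelvis_motion = 0)
  expect_equal(rolls$sacrum$values_deg, rep(0, n))
  expect_equal(rolls$thigh$values_deg, rep(-30, n))
  expect_equal(rolls$shank$values_deg, rep(-50, n))
  # round-trip through the joint model for arbitrary trajectories
  tr <- generate_truth(gait_profile(), 10, 60, seed = 3)
  pel <- 2 * sin(seq_len(tr$hip$n) / 9)
  r <- truth_to_segment_rolls(tr$hip, tr$knee, pelvis_motion = pel)
  expect_equal(hip_flexion(r$sacrum, r$thigh)$values_deg, tr$hip$values_deg,
               tolerance = 1e-12)
  expect_equal(knee_flexion(r$thigh, r$shank)$values_deg, tr$knee$values_deg,
               tolerance = 1e-12)
  # common-mode: shifting every roll leaves the recovered joints unchanged
  shift <- function(x, c0) roll_series(x$sensor_id, x$values_deg + c0, x$rate_hz)
  expect_equal(hip_flexion(shift(r$sacrum, 33), shift(r$thigh, 33))$values_deg,
               tr$hip$values_deg, tolerance = 1e-12)
})

test_that("zero-noise corruption is transparent through quaternions", {
  tr <- generate_truth(gait_profile(), 10, 60, seed = 4)
  rolls <- truth_to_segment_rolls(tr$hip, tr$knee)
  clean <- sensor_noise_model(white_sd_deg = 0, drift_deg_per_min = 0,
                              soft_tissue_gain = 0,
                              heading_deg = c(10, -50, 120))
  streams <- corrupt_rolls(rolls, clean, "T1")
  for (id in c("sacrum", "thigh", "shank")) {
    expect_equal(extract_roll_series(streams[[id]])$values_deg,
                 rolls[[id]]$values_deg, tolerance = 1e-9)
  }
})

test_that("white noise and drift appear at their configured magnitudes", {
  n_s <- 200  # 200 s at 60 Hz -> 12,000 samples
  flat <- gait_profile(hip_harmonics = list(c(0, 0)),
                       knee_harmonics = list(c(0, 0)), cycle_jitter_cv = 0)
  tr <- generate_truth(flat, n_s, 60, seed = 5)
  rolls <- truth_to_segment_rolls(tr$hip, tr$knee)
  noisy <- sensor_noise_model(white_sd_deg = 1, drift_deg_per_min = 0,
                              soft_tissue_gain = 0, seed = 6)
  out <- corrupt_rolls(rolls, noisy, "T1")
  resid <- extract_roll_series(out$sacrum)$values_deg - rolls$sacrum$values_deg
  expect_gt(sd(resid), 0.95)
  expect_lt(sd(resid), 1.05)
  expect_lt(abs(mean(resid)), 3 / sqrt(12000))

  drifty <- sensor_noise_model(white_sd_deg = 0.1, drift_deg_per_min = 1,
                               soft_tissue_gain = 0, seed = 7)
  tr60 <- generate_truth(flat, 60, 60, seed = 8)
  rolls60 <- truth_to_segment_rolls(tr60$hip, tr60$knee)
  out60 <- corrupt_rolls(rolls60, drifty, "T1")
  r <- extract_roll_series(out60$thigh)$values_deg
  ends <- mean(tail(r, 60)) - mean(head(r, 60))
  expect_equal(ends, 1, tolerance = 0.15)  # 1 deg/min over ~59.5 s
})

test_that("T2 offset shift and static offsets act on the right sensors", {
  tr <- generate_truth(gait_profile(), 5, 60, seed = 9)
  rolls <- truth_to_segment_rolls(tr$hip, tr$knee)
  nm <- sensor_noise_model(static_offset_deg = c(1, -2, 0.5),
                           t2_offset_shift_deg = c(0, 0.5, -2),
                           white_sd_deg = 0, drift_deg_per_min = 0,
                           soft_tissue_gain = 0)
  t1 <- corrupt_rolls(rolls, nm, "T1")
  t2 <- corrupt_rolls(rolls, nm, "T2")
  expect_equal(extract_roll_series(t1$thigh)$values_deg,
               rolls$thigh$values_deg - 2, tolerance = 1e-9)
  expect_equal(extract_roll_series(t2$thigh)$values_deg,
               rolls$thigh$values_deg - 1.5, tolerance = 1e-9)
  expect_equal(extract_roll_series(t2$sacrum)$values_deg,
               rolls$sacrum$values_deg + 1, tolerance = 1e-9)
})

test_that("cohorts are reproducible and carry the protocol dimensions", {
  a <- simulate_cohort(2, trial_duration_s = 30, seed = 10)
  b <- simulate_cohort(2, trial_duration_s = 30, seed = 10)
  c <- simulate_cohort(2, trial_duration_s = 30, seed = 11)
  expect_identical(a$participants$P01$T1$truth_hip$values_deg,
                   b$participants$P01$T1$truth_hip$values_deg)
  expect_identical(unclass(a$participants$P02$T2$sensors$shank$quaternions),
                   unclass(b$participants$P02$T2$sensors$shank$quaternions))
  expect_false(identical(a$participants$P01$T1$truth_hip$values_deg,
                         c$participants$P01$T1$truth_hip$values_deg))
  p <- a$participants$P01
  expect_identical(p$T1$truth_hip$n, 1800L)
  expect_identical(p$calibration$sensors$sacrum$n, 600L)  # 10 s at 60 Hz
  expect_identical(length(a$manifest), 2L)
  expect_identical(a$manifest[["P01"]]$lag_T1, p$params$lag_T1)
})

test_that("a cohort round-trips through the CSV + manifest writer", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(1, trial_duration_s = 5, seed = 12)
  write_cohort(co, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(man$seed, 12L)
  expect_identical(length(man$participants), 1L)
  streams <- read_orientation_csv(file.path(dir, "P01_T1_sensors.csv"))
  expect_setequal(names(streams), c("sacrum", "thigh", "shank"))
  expect_equal(unclass(streams$thigh$quaternions),
               unclass(co$participants$P01$T1$sensors$thigh$quaternions),
               tolerance = 1e-9)
  refs <- read_joint_angles_csv(file.path(dir, "P01_T1_reference.csv"))
  expect_equal(refs$hip.reference.raw$values_deg,
               co$participants$P01$T1$reference_hip$values_deg,
               tolerance = 1e-9)
})

test_that("the session scheduler reproduces the walking protocol", {
  sched <- session_schedule()
  expect_identical(attr(sched, "total_min"), 41)
  expect_identical(nrow(sched), 7L)  # 4 bouts + 3 rests
  expect_identical(sched$end_min[7], 41)
  short <- session_schedule(n_bouts = 2, bout_duration_min = 5,
                            rest_duration_min = 2)
  expect_identical(attr(short, "total_min"), 12)
})
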