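test_that("differentiation is exact on polynomials and accurate on sinusoids", {
  t <- seq(0, 2, by = 0.01)
  expect_equal(differentiate(3.5 * t, 100, smooth = FALSE), rep(3.5, length(t)))
  expect_equal(differentiate(rep(2, 201), 100, smooth = FALSE), rep(0, 201))
  expect_error(differentiate(c(1, 2), 100), "3 samples")

  # theta(t) = A sin(2 pi f t): max |dtheta/dt| = 2 pi f A
  t <- seq(0, 10, by = 0.01)
  theta <- 0.8 * sin(2 * pi * 0.5 * t)
  d <- differentiate(theta, 100, smooth = TRUE)
  expect_equal(max(abs(d)), 2 * pi * 0.5 * 0.8, tolerance = 0.01)
})

test_that("joint angles follow the sagittal sign convention", {
  n <- 50
  ja <- joint_angles(rep(0.3, n), rep(0.1, n), rep(0.4, n))
  expect_equal(ja$hip, rep(0.2, n))
  expect_equal(ja$knee, rep(-0.3, n))
  expect_equal(joint_angles(rep(0.5, n), rep(0.5, n), rep(0.1, n))$hip, rep(0, n))
  expect_error(joint_angles(1:5, 1:4, 1:5), "equal length")
})

test_that("angular and vertical power follow their defining products", {
  expect_equal(angular_power(1, 0, 5), 0)
  expect_equal(angular_power(2, 3, 4), 24)
  expect_equal(angular_power(0.5, -2, 3), -3)
  expect_error(angular_power(-1, 1, 1), "non-negative")
  expect_equal(vertical_power(70, 0, 3), 0)
  expect_equal(vertical_power(70, 0.5, 2), 70)
  expect_error(vertical_power(0, 1, 1), "positive")
})

test_that("scaled vertical power matches its normalization identities", {
  g <- 9.81
  for (mh in list(c(70, 1.70), c(55, 1.55))) {
    expect_equal(scaled_vertical_power(mh[1] * g^2 * mh[2], mh[1], mh[2]), 1)
  }
  expect_equal(scaled_vertical_power(11452.1, 70, 1.70), 1, tolerance = 1e-3)
  expect_equal(scaled_vertical_power(70 * g * sqrt(g * 1.7), 70, 1.7,
                                     form = "conventional"), 1)
  expect_error(scaled_vertical_power(1, -1, 1.7), "positive")
})

test_that("segment inertia scales with mass and height squared", {
  expect_gt(segment_inertia("trunk", 70, 1.7), segment_inertia("shank", 70, 1.7))
  expect_equal(segment_inertia("thigh", 140, 1.7),
               2 * segment_inertia("thigh", 70, 1.7))
  expect_equal(segment_inertia("thigh", 70, 3.4),
               4 * segment_inertia("thigh", 70, 1.7))
})

test_that("segmentation recovers the generated cycles", {
  prof <- subject_profile(0, cycle_duration = 1.2, pause_duration = 0.3,
                          cycle_cv = 0, noise_sd = 0)
  rec <- generate_recording(prof, seed = 1)
  b <- segment_cycles(rec)
  expect_true(b$valid)
  expect_equal(b$n_cycles, 5L)
  lens <- (b$intervals$end - b$intervals$start) / rec$sampling_rate
  expect_true(all(abs(lens - 1.2) <= 1 / rec$sampling_rate))

  # no movement: invalid trial with zero cycles
  flat <- rec
  flat$data$thigh_pitch_rad[] <- 1.4
  bf <- segment_cycles(flat)
  expect_false(bf$valid)
  expect_equal(bf$n_cycles, 0L)
  err <- tryCatch(extract_features(flat), sts_invalid_trial = function(e) e)
  expect_s3_class(err, "sts_invalid_trial")
  expect_equal(err$n_cycles, 0L)

  # noisy, jittered recordings still segment into 5 cycles
  for (s in 1:5) {
    recn <- generate_recording(subject_profile(1, cycle_cv = 0.1, noise_sd = 0.02),
                               seed = s)
    expect_equal(segment_cycles(recn)$n_cycles, 5L)
  }
})

test_that("extraction recovers closed-form kinematics on noiseless recordings", {
  for (s in c(2, 7)) {
    prof <- subject_profile(1, cycle_cv = 0.08, noise_sd = 0)
    rec <- generate_recording(prof, seed = s)
    tr <- recording_truth(rec)
    b <- segment_cycles(rec)
    fv <- extract_features(rec, b)
    lens <- (b$intervals$end - b$intervals$start) / rec$sampling_rate
    expect_true(all(abs(lens - tr$duration_s) <= 1 / rec$sampling_rate))
    expect_equal(fv$mean_hip_angle_range, mean(tr$hip_angle_range), tolerance = 0.02)
    expect_equal(fv$mean_hip_angular_velocity_range,
                 mean(tr$hip_angular_velocity_range), tolerance = 0.02)
    expect_equal(fv$mean_knee_angular_velocity_range,
                 mean(tr$knee_angular_velocity_range), tolerance = 0.02)
    expect_equal(fv$mean_vertical_velocity_range,
                 mean(tr$vertical_velocity_range), tolerance = 0.02)
  }
})

test_that("feature vector has 17 named entries with zero CVs for identical cycles", {
  rec <- generate_recording(subject_profile(0, cycle_cv = 0, noise_sd = 0), seed = 4)
  fv <- extract_features(rec)
  expect_identical(setdiff(names(fv), c("subject_id", "status")), sts_feature_names())
  cvs <- unlist(fv[grep("^cv_", names(fv))])
  expect_true(all(cvs == 0))
  ranges <- unlist(fv[grep("^mean_", names(fv))])
  expect_true(all(ranges >= 0))
})

test_that("per-cycle summary behaves like sample-SD CV with scale invariance", {
  cv <- stsfrailty:::.guarded_cv
  expect_equal(cv(c(2, 4)), stats::sd(c(2, 4)) / 3)
  expect_equal(cv(c(2, 4)), 0.4714, tolerance = 1e-4)
  x <- c(1.1, 1.4, 0.9, 1.2, 1.3)
  expect_equal(cv(7 * x), cv(x))      # CV unchanged under scaling
  expect_equal(mean(7 * x), 7 * mean(x))
  expect_true(is.na(cv(c(-1, 1))))    # near-zero mean: CV undefined
  expect_equal(cv(rep(3, 5)), 0)
})

test_that("time-stretched movement lengthens duration and slows velocities", {
  k <- 1.5
  base <- subject_profile(0, cycle_duration = 1.2, pause_duration = 0.3,
                          cycle_cv = 0, noise_sd = 0)
  slow <- subject_profile(0, cycle_duration = 1.2 * k, pause_duration = 0.3 * k,
                          cycle_cv = 0, noise_sd = 0)
  f1 <- extract_features(generate_recording(base, seed = 6))
  f2 <- extract_features(generate_recording(slow, seed = 6))
  expect_equal(f2$sts_duration / f1$sts_duration, k, tolerance = 0.02)
  expect_equal(f2$mean_hip_angular_velocity_range / f1$mean_hip_angular_velocity_range,
               1 / k, tolerance = 0.03)
  expect_equal(f2$mean_knee_angular_velocity_range / f1$mean_knee_angular_velocity_range,
               1 / k, tolerance = 0.03)
})
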