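# Drift-angle estimation from quasi-static accelerometer recordings.

test_that("smoothing a constant signal is the identity", {
  rec <- const_recording()
  sm <- smooth_recording(rec, 0.5)
  expect_equal(sm$ax, rec$ax)
  expect_equal(sm$az, rec$az)
})

test_that("window_s = 0 returns the recording unchanged", {
  rec <- const_recording(c(0.1, -0.2, -0.9))
  expect_identical(smooth_recording(rec, 0), rec)
})

test_that("2-sample window zeroes an alternating signal in the interior", {
  t <- seq(0, 20, by = 1 / 50)
  ax <- rep_len(c(0.1, -0.1), length(t))
  rec <- limb_recording(t, ax, rep(0, length(t)), rep(-1, length(t)),
                        sample_rate_hz = 50)
  sm <- smooth_recording(rec, 2 / 50)
  expect_equal(sm$ax[-length(t)], rep(0, length(t) - 1))
})

test_that("smoothing rejects invalid input", {
  rec <- const_recording()
  expect_error(smooth_recording(rec, -1), class = "dg_invalid_input")
  expect_error(smooth_recording(data.frame(), 0.5),
               class = "dg_invalid_input")
})

test_that("reference orientation is the normalized window mean", {
  ref <- estimate_reference_orientation(const_recording(c(0, 0, -1)))
  expect_equal(ref$gravity_dir, c(0, 0, -1))

  ref2 <- estimate_reference_orientation(const_recording(c(0.1, 0, -1)))
  expect_equal(ref2$gravity_dir, c(0.1, 0, -1) / sqrt(1.01), tolerance = 1e-12)
  expect_equal(sqrt(sum(ref2$gravity_dir^2)), 1, tolerance = 1e-12)
})

test_that("zero-mean calibration window is a degenerate-calibration error", {
  t <- seq(0, 19.5, by = 0.5)  # even sample count: alternation cancels
  ax <- rep_len(c(1, -1), length(t))
  rec <- limb_recording(t, ax, rep(0, length(t)), rep_len(c(1, -1), length(t)),
                        sample_rate_hz = 2)
  expect_error(estimate_reference_orientation(rec, c(0, 20)),
               class = "dg_degenerate_calibration")
})

test_that("static recording at the reference pose has zero drift", {
  rec <- const_recording(c(0, 0, -1))
  ref <- estimate_reference_orientation(rec)
  ser <- compute_drift_series(rec, ref, smoothing_s = 0.5)
  expect_equal(ser$theta_drift, rep(0, nrow(rec)))
})

test_that("a 30-degree downward pitch gives theta_drift = -30", {
  # closed form: elevation = asin(g_x); reference elevation 0
  rec <- const_recording(c(-sin(pi / 6), 0, -cos(pi / 6)))
  ref <- structure(list(gravity_dir = c(0, 0, -1)), class = "orientation")
  ser <- compute_drift_series(rec, ref, smoothing_s = 0)
  expect_equal(ser$theta_drift, rep(-30, nrow(rec)), tolerance = 1e-9)
})

test_that("noise-free simulated trajectories are recovered within 0.5 degrees", {
  profiles <- list(
    drift_profile(1, 7, drop_rate_deg_per_s = 2, drop_onset_s = 5,
                  osc_amp_deg = 10, osc_freq_hz = 0.7, noise_sd_g = 0),
    drift_profile(0, 9, osc_amp_deg = 3, osc_freq_hz = 1.5, noise_sd_g = 0),
    drift_profile(1, 8, hold_angle = 80, drop_rate_deg_per_s = 0.5,
                  drop_onset_s = 3, osc_amp_deg = 4, noise_sd_g = 0))
  for (prof in profiles) {
    sim <- simulate_recording(prof)
    ser <- compute_drift_series(sim$recording, smoothing_s = 0)
    expect_lt(max(abs(ser$theta_drift - sim$truth$theta_drift)), 0.5)
  }
})

test_that("noisy recovery with smoothing stays within 2 degrees", {
  prof <- drift_profile(1, 7, drop_rate_deg_per_s = 1.5, drop_onset_s = 6,
                        osc_amp_deg = 3, osc_freq_hz = 0.4,
                        noise_sd_g = 0.02, seed = 7)
  sim <- simulate_recording(prof)
  ser <- compute_drift_series(sim$recording, smoothing_s = 0.5)
  expect_lt(max(abs(ser$theta_drift - sim$truth$theta_drift)), 2)
})

test_that("drift is invariant to uniform rescaling of the acceleration", {
  prof <- drift_profile(1, 7, drop_rate_deg_per_s = 1, drop_onset_s = 4,
                        osc_amp_deg = 5, noise_sd_g = 0.01, seed = 3)
  rec <- simulate_recording(prof)$recording
  scaled <- limb_recording(rec$t, 3.7 * rec$ax, 3.7 * rec$ay, 3.7 * rec$az,
                           limb_id = attr(rec, "limb_id"),
                           sample_rate_hz = attr(rec, "sample_rate_hz"))
  s1 <- compute_drift_series(rec, smoothing_s = 0.5)
  s2 <- suppressMessages(compute_drift_series(scaled, smoothing_s = 0.5))
  expect_equal(s1$theta_drift, s2$theta_drift, tolerance = 1e-9)
})

test_that("drift over the calibration window averages to zero (noise-free hold)", {
  prof <- drift_profile(0, 8, drop_rate_deg_per_s = 0.2, drop_onset_s = 12,
                        osc_amp_deg = 0, noise_sd_g = 0)
  sim <- simulate_recording(prof)
  ser <- compute_drift_series(sim$recording, smoothing_s = 0)
  cal <- ser$t >= 0 & ser$t <= 2
  expect_lt(abs(mean(ser$theta_drift[cal])), 1e-6)
})

test_that("time shift moves t and leaves theta unchanged", {
  prof <- drift_profile(1, 7, drop_rate_deg_per_s = 1, drop_onset_s = 5,
                        noise_sd_g = 0)
  rec <- simulate_recording(prof)$recording
  shifted <- limb_recording(rec$t + 3.25, rec$ax, rec$ay, rec$az,
                            sample_rate_hz = attr(rec, "sample_rate_hz"))
  ref <- estimate_reference_orientation(rec, c(0, 2))
  s1 <- compute_drift_series(rec, ref, smoothing_s = 0.5)
  s2 <- compute_drift_series(shifted, ref, smoothing_s = 0.5)
  expect_equal(s2$t, s1$t + 3.25)
  expect_equal(s2$theta_drift, s1$theta_drift)
})

test_that("unusable frames warn, and too many of them abort", {
  t <- seq(0, 20, by = 0.1)
  n <- length(t)
  az <- rep(-1, n)
  az[5] <- 0  # one zero-norm frame
  rec <- suppressMessages(
    limb_recording(t, rep(0, n), rep(0, n), az, sample_rate_hz = 10))
  ref <- structure(list(gravity_dir = c(0, 0, -1)), class = "orientation")
  expect_warning(ser <- compute_drift_series(rec, ref, smoothing_s = 0),
                 class = "dg_frames_skipped")
  expect_equal(nrow(ser), n - 1L)

  az_bad <- rep(-1, n)
  az_bad[seq_len(ceiling(0.2 * n))] <- 0
  rec_bad <- suppressMessages(
    limb_recording(t, rep(0, n), rep(0, n), az_bad, sample_rate_hz = 10))
  expect_error(suppressWarnings(
    compute_drift_series(rec_bad, ref, smoothing_s = 0)),
    class = "dg_invalid_recording")
})

test_that("recording CSV round-trips through write/read with filename metadata", {
  prof <- drift_profile(0, 9, osc_amp_deg = 2, noise_sd_g = 0.01, seed = 5)
  rec <- simulate_recording(prof, limb_id = "LRL", subject_id = "S99")$recording
  path <- file.path(tempdir(), "S99_LRL.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$ax, rec$ax, tolerance = 1e-12)
  expect_identical(attr(back, "limb_id"), "LRL")
  expect_identical(attr(back, "subject_id"), "S99")
  unlink(path)
})
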