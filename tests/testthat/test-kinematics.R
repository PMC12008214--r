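# Amplitude pipeline: band-pass, displacement, turning points, swings,
# calibration, and the composed estimator.

test_that("band-pass passes the tremor band and rejects drift and DC", {
  fs <- 120
  t <- seq(0, 30, by = 1 / fs)
  tone <- sin(2 * pi * 6 * t)
  out <- bandpass(tone, fs)
  mid <- out[500:3000]
  expect_equal(max(abs(mid)), 1, tolerance = 0.05)

  drift <- 100 * sin(2 * pi * 0.3 * t)
  expect_lt(max(abs(bandpass(drift, fs))), 5)

  flat <- bandpass(rep(3.7, 1000), fs)
  expect_lt(max(abs(flat)), 1e-6)

  expect_error(bandpass(tone, fs, low = 5, high = 3),
               class = "tremorcv_error_band")
  expect_error(bandpass(tone[1:10], fs), class = "tremorcv_error_too_short")
})

test_that("consecutive displacement is the per-frame Euclidean step", {
  n <- 200L
  static <- make_trace_12(matrix(5, n, 3L))
  d <- consecutive_displacement(static, "OMC_XYZ")
  expect_equal(length(d$raw), n - 1L)
  expect_equal(max(d$raw), 0)

  steps_1d <- make_trace_12(cbind(3 * (seq_len(n) - 1), 0, 0))
  expect_equal(unique(consecutive_displacement(steps_1d, "OMC_XYZ")$raw), 3)

  steps_2d <- make_trace_12(cbind(3 * (seq_len(n) - 1), 4 * (seq_len(n) - 1), 0))
  expect_equal(unique(consecutive_displacement(steps_2d, "OMC_XYZ")$raw), 5)

  one_frame <- make_trace_12(matrix(0, 5, 3L),
                             detected = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_error(consecutive_displacement(one_frame, "OMC_XYZ"),
               class = "tremorcv_error_too_few_frames")
})

test_that("turning points sit at the motion reversals of a sinusoid", {
  fs <- 120
  t <- (0:(30 * fs - 1)) / fs
  x <- 10 * sin(2 * pi * 6 * t)
  tr <- make_trace_12(cbind(x, 0, 0))
  d <- consecutive_displacement(tr, "OMC_XYZ")
  tp <- detect_turning_points(d)
  # 2 reversals per cycle over 30 s at 6 Hz
  expect_lte(abs(length(tp) - 360L), 1L)
  # each reversal step straddles a positional extreme (within one sample)
  straddle <- pmax(abs(x[tp]), abs(x[tp + 1L]))
  expect_gt(min(straddle / 10), 0.97)

  ramp <- make_trace_12(cbind(seq(0, 100, length.out = 600), 0, 0))
  expect_length(detect_turning_points(consecutive_displacement(ramp, "OMC_XYZ")),
                0L)

  # two cycles -> 4 interior reversals (within boundary effects)
  t2 <- (0:59) / fs
  two <- make_trace_12(cbind(10 * sin(2 * pi * 4 * t2), 0, 0))
  tp2 <- detect_turning_points(consecutive_displacement(two, "OMC_XYZ"))
  expect_lte(abs(length(tp2) - 4L), 1L)
})

test_that("turning points match the brute-force windowed-minimum oracle", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(40:300, 1L)
    # band-limited random displacement-like signal
    raw <- abs(bandpass(stats::rnorm(n + 200), 120, 2, 10))[101:(100 + n)]
    d <- make_displacement(raw)
    expect_identical(detect_turning_points(d),
                     oracle_turning_points(raw, 120, 10))
  }
})

test_that("swing amplitude of a sinusoid is its peak-to-peak path length", {
  # 240 Hz sampling keeps the discretized path within the tolerance for all
  # tested frequencies (an integer number of samples per half-cycle)
  fs <- 240
  for (f in c(4, 6, 8)) {
    for (A in c(1, 10)) {
      t <- (0:(30 * fs - 1)) / fs
      tr <- make_trace_12(cbind(A * sin(2 * pi * f * t), 0, 0),
                          sample_rate = fs)
      sw <- estimate_amplitude(tr, "OMC_XYZ")
      expect_true(sw$estimable)
      expect_equal(sw$median_amplitude, 2 * A, tolerance = 0.02)
    }
  }
  # at the 120 Hz video rate an 8 Hz tremor (7.5 samples per half-cycle)
  # alternates 7- and 8-sample swings: the median then sits within ~3% of 2A
  t <- (0:(30 * 120 - 1)) / 120
  tr <- make_trace_12(cbind(10 * sin(2 * pi * 8 * t), 0, 0))
  expect_equal(estimate_amplitude(tr, "OMC_XYZ")$median_amplitude, 20,
               tolerance = 0.035)
})

test_that("swings of a symmetric closed orbit are all equal", {
  fs <- 120
  t <- (0:(20 * fs - 1)) / fs
  # elliptic orbit at 5 Hz: two equal swings per revolution by symmetry
  # (phase offset avoids exactly tied displacement minima)
  tr <- make_trace_12(cbind(10 * cos(2 * pi * 5 * t + 0.37),
                            6 * sin(2 * pi * 5 * t + 0.37), 0))
  sw <- estimate_amplitude(tr, "OMC_XYZ")
  expect_true(sw$estimable)
  # interior swings (the first/last ones touch the filter's edge transients)
  inner <- sw$swing_amplitudes[3:(length(sw$swing_amplitudes) - 2L)]
  expect_lt(stats::sd(inner) / mean(inner), 0.01)
  expect_equal(sw$median_amplitude, mean(inner), tolerance = 0.01)
})

test_that("scale calibration converts marker extent to mm per px", {
  cal <- calibrate_scale(c(19, 19))
  expect_equal(cal$mm_per_px, c(0.5, 0.5))
  expect_error(calibrate_scale(c(0, 5)), class = "tremorcv_error_calibration")

  # doubling the focal length doubles the marker extent, halving mm/px
  world <- simulate_hand_trajectory(sim_config(duration = 1))
  cam1 <- camera_model(0, -90, focal_length = 1500)
  cam2 <- camera_model(0, -90, focal_length = 3000)
  e1 <- colMeans(attr(project_to_camera(world, cam1), "marker_extent_px"))
  e2 <- colMeans(attr(project_to_camera(world, cam2), "marker_extent_px"))
  expect_equal(e2, 2 * e1, tolerance = 1e-9)
  expect_equal(calibrate_scale(e2)$mm_per_px, calibrate_scale(e1)$mm_per_px / 2,
               tolerance = 1e-9)
})

test_that("calibrated pixel amplitude recovers the true in-plane amplitude", {
  cfg <- sim_config(tremor_axis = c(1, 0, 0), amplitude_start = 10)
  world <- simulate_hand_trajectory(cfg)
  px <- project_to_camera(world, camera_model(0, -90))
  cal <- calibrate_scale(colMeans(attr(px, "marker_extent_px")))
  sw <- estimate_amplitude(px, "VI_XY", calibration = cal)
  expect_equal(sw$median_amplitude, 20, tolerance = 0.1)
  expect_identical(sw$units, "mm")
  # uncalibrated pixel estimates stay in native units
  expect_identical(estimate_amplitude(px, "VI_XY")$units, "px")
})

test_that("variant unit handling: world_m traces are scaled to mm", {
  fs <- 120
  t <- (0:(10 * fs - 1)) / fs
  pos_m <- cbind(0.01 * sin(2 * pi * 6 * t), 0, 0)  # 10 mm in meters
  tr <- make_trace_12(pos_m, space = "world_m")
  sw <- estimate_amplitude(tr, "MP_WORLD_XY")
  expect_equal(sw$median_amplitude, 20, tolerance = 0.02)
  expect_identical(sw$units, "mm")
})

test_that("median amplitude is exactly scale-equivariant", {
  fs <- 120
  t <- (0:(10 * fs - 1)) / fs
  x <- cbind(7 * sin(2 * pi * 5 * t), 3 * cos(2 * pi * 5 * t), 0)
  tr1 <- make_trace_12(x)
  tr3 <- make_trace_12(3 * x)
  m1 <- estimate_amplitude(tr1, "OMC_XYZ")$median_amplitude
  m3 <- estimate_amplitude(tr3, "OMC_XYZ")$median_amplitude
  expect_equal(m3, 3 * m1, tolerance = 1e-12)
})

test_that("median amplitude is invariant under 3D rotation", {
  fs <- 120
  t <- (0:(10 * fs - 1)) / fs
  x <- cbind(10 * sin(2 * pi * 6 * t), 4 * sin(2 * pi * 6 * t + 1), 0)
  th <- 0.7; ph <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  m1 <- estimate_amplitude(make_trace_12(x), "OMC_XYZ")$median_amplitude
  m2 <- estimate_amplitude(make_trace_12(x %*% (Rz %*% Rx)),
                           "OMC_XYZ")$median_amplitude
  expect_equal(m2, m1, tolerance = 1e-9)
})

test_that("pixel amplitude decreases as the tremor tilts toward the optical axis", {
  cam <- camera_model(0, -90)
  amps <- vapply(c(0, 30, 60, 85), function(phi) {
    ax <- c(cos(phi * pi / 180), 0, sin(phi * pi / 180))
    world <- simulate_hand_trajectory(sim_config(tremor_axis = ax,
                                                 amplitude_start = 10,
                                                 duration = 10))
    estimate_amplitude(project_to_camera(world, cam), "VI_XY")$median_amplitude
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("gap handling interpolates short gaps and segments long ones", {
  fs <- 120
  t <- (0:(30 * fs - 1)) / fs
  x <- cbind(10 * sin(2 * pi * 6 * t), 0, 0)
  det <- rep(TRUE, length(t))
  det[1000:1020] <- FALSE                       # 0.175 s: interpolated
  tr <- make_trace_12(x, detected = det)
  d <- consecutive_displacement(tr, "OMC_XYZ")
  expect_equal(length(unique(d$segment)), 1L)
  expect_equal(d$n_interpolated, 21L)

  det2 <- rep(TRUE, length(t))
  det2[1000:1200] <- FALSE                      # 1.7 s: split into segments
  tr2 <- make_trace_12(x, detected = det2)
  d2 <- consecutive_displacement(tr2, "OMC_XYZ")
  expect_equal(length(unique(d2$segment)), 2L)
  sw2 <- estimate_amplitude(tr2, "OMC_XYZ")
  expect_equal(sw2$median_amplitude, 20, tolerance = 0.02)

  undet <- make_trace_12(x, detected = rep(FALSE, length(t)))
  sw3 <- estimate_amplitude(undet, "OMC_XYZ")
  expect_false(sw3$estimable)
  expect_true(is.na(sw3$median_amplitude))
})
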