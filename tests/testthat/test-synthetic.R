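# The synthetic tremulous-hand generator: trajectory construction, camera
# projection, tracking noise, IMU synthesis, cohort sampling.

test_that("fingertip oscillation realizes the configured amplitude envelope", {
  cfg <- sim_config(tremor_frequency = 6, amplitude_start = 10)
  tr <- simulate_hand_trajectory(cfg)
  x <- landmark_positions(tr, 12)
  along_axis <- x %*% cfg$tremor_axis   # palm normal == world z here
  # 120 Hz samples a 6 Hz tone exactly at its extremes
  expect_equal(diff(range(along_axis)), 20, tolerance = 1e-9)

  ramp <- simulate_hand_trajectory(sim_config(amplitude_start = 0,
                                              amplitude_end = 20))
  env <- attr(ramp, "envelope_mm")
  mid <- which.min(abs(ramp$timestamps - 15))
  expect_equal(env[mid], 10, tolerance = 0.01)
  expect_equal(env[1L], 0)
  expect_equal(env[length(env)], 20)
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(frequency_jitter_sd = 0.3, amplitude_noise_cv = 0.1,
                    seed = 42L)
  expect_identical(simulate_hand_trajectory(cfg)$positions,
                   simulate_hand_trajectory(cfg)$positions)
  sc1 <- synthesize_scene(cfg, noise = noise_model(seed = 7L))
  sc2 <- synthesize_scene(cfg, noise = noise_model(seed = 7L))
  expect_identical(sc1$mp_norm$positions, sc2$mp_norm$positions)
  expect_identical(sc1$imu$accel, sc2$imu$accel)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(tremor_frequency = 70, sample_rate = 120),
               class = "tremorcv_error_config")
  expect_error(sim_config(amplitude_start = -1), class = "tremorcv_error_config")
  expect_error(sim_config(tremor_axis = c(1, 1, 0)),
               class = "tremorcv_error_config")
  expect_error(camera_model(distance = 0), class = "tremorcv_error_config")
  expect_error(noise_model(dropout_threshold = 2),
               class = "tremorcv_error_config")
})

test_that("pinhole projection maps the scene center to the principal point", {
  n <- 5L
  center <- c(100, 50, 20)
  pos <- array(rep(center, each = n), dim = c(n, 1L, 3L))
  tr <- trajectory_trace((0:(n - 1)) / 120, pos, "world_mm",
                         landmark_ids = 12L, sample_rate = 120)
  attr(tr, "scene_center_mm") <- center
  for (cam in list(camera_model(0, 0), camera_model(-45, -60),
                   camera_model(30, -90))) {
    px <- project_to_camera(tr, cam)
    expect_equal(px$positions[1L, 1L, ], cam$principal_point,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("projected amplitude follows pinhole similar-triangles geometry", {
  # tremor along the optical axis: near-zero in-plane excursion
  top_down <- camera_model(azimuth = 0, elevation = -90)
  axial <- simulate_hand_trajectory(sim_config(tremor_axis = c(0, 0, 1)))
  px <- project_to_camera(axial, top_down)
  tip <- landmark_positions(px, 12)
  expect_lt(max(apply(tip, 2L, function(v) diff(range(v)))), 1.5)

  # tremor in the image plane: half-amplitude = focal * A / depth
  in_plane <- simulate_hand_trajectory(sim_config(tremor_axis = c(1, 0, 0),
                                                  amplitude_start = 10))
  px2 <- project_to_camera(in_plane, top_down)
  tip2 <- landmark_positions(px2, 12)
  depth <- mean(attr(px2, "camera_depth_mm")[, match(12, px2$landmark_ids)])
  expected_half <- top_down$focal_length * 10 / depth   # ~10 px at 1.5 m
  expect_equal(diff(range(tip2[, 1L])) / 2, expected_half, tolerance = 0.01)
  expect_equal(expected_half, 10, tolerance = 0.01)
})

test_that("points behind the camera are rejected with the frame index", {
  n <- 3L
  pos <- array(0, dim = c(n, 1L, 3L))
  pos[, 1L, 2L] <- c(0, 4000, 0)   # frame 2 passes behind a 1.5 m camera
  tr <- trajectory_trace((0:(n - 1)) / 120, pos, "world_mm",
                         landmark_ids = 12L, sample_rate = 120)
  attr(tr, "scene_center_mm") <- c(0, 0, 0)
  expect_error(project_to_camera(tr, camera_model(0, 0)),
               regexp = "frame 2", class = "tremorcv_error_projection")
})

test_that("frame normalization divides by the resolution and round-trips", {
  n <- 4L
  pos <- array(0, dim = c(n, 1L, 2L))
  pos[, 1L, 1L] <- c(960, 0, 1920, 123.4)
  pos[, 1L, 2L] <- c(540, 0, 1080, 77.7)
  tr <- trajectory_trace((0:(n - 1)) / 120, pos, "pixel", landmark_ids = 12L,
                         frame_resolution = c(1920, 1080))
  nm <- normalize_to_frame(tr)
  expect_equal(nm$positions[1L, 1L, ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(nm$positions[2L, 1L, ], c(0, 0), ignore_attr = TRUE)
  back <- denormalize_from_frame(nm)
  expect_equal(back$positions, tr$positions)
})

test_that("tracking confidence follows the palm-view geometry", {
  world <- simulate_hand_trajectory(sim_config())
  cam <- camera_model(0, -45)
  flat <- noise_model(confidence_view_exponent = 0, confidence_noise_sd = 0,
                      dropout_threshold = 0, jitter_sd_px = 0, jitter_sd_mm = 0)
  tr <- apply_tracking_noise(world, flat, cam)
  expect_true(all(tr$detected))
  expect_equal(unique(tr$confidence), flat$confidence_base)

  # viewing direction in the palm plane: cos(theta) = 0, everything drops out
  frontal <- camera_model(0, 0)
  strict <- noise_model(confidence_noise_sd = 0, dropout_threshold = 0.1)
  tr2 <- apply_tracking_noise(world, strict, frontal)
  expect_false(any(tr2$detected))
  expect_true(all(is.na(tr2$positions[, , 1L])))
})

test_that("jitter realizes its configured marginal SD", {
  world <- simulate_hand_trajectory(sim_config(amplitude_start = 0))
  px <- project_to_camera(world, camera_model(0, -90))
  nm <- noise_model(jitter_sd_px = 1, jitter_correlation_s = 0,
                    confidence_noise_sd = 0, dropout_threshold = 0, seed = 5L)
  noised <- apply_tracking_noise(px, nm, camera_model(0, -90))
  added <- noised$positions[, , 1L] - px$positions[, , 1L]
  expect_equal(stats::sd(added), 1, tolerance = 0.05)

  # AR(1) jitter keeps the marginal SD
  nm2 <- noise_model(jitter_sd_px = 1, jitter_correlation_s = 0.05,
                     confidence_noise_sd = 0, dropout_threshold = 0, seed = 5L)
  noised2 <- apply_tracking_noise(px, nm2, camera_model(0, -90))
  added2 <- noised2$positions[, , 1L] - px$positions[, , 1L]
  expect_equal(stats::sd(added2), 1, tolerance = 0.1)
})

test_that("synthesized IMU matches rigid-body closed forms", {
  static <- simulate_hand_trajectory(sim_config(amplitude_start = 0))
  imu <- synthesize_imu(static, noise_sd = 0)
  norms <- sqrt(rowSums(imu$accel^2))
  expect_equal(range(norms), c(9.81, 9.81), tolerance = 1e-6)
  expect_equal(imu$sample_rate, 200)

  # x(t) = A sin(w t) => peak acceleration A w^2 = 14.2 m/s^2 for A=10mm, 6 Hz
  shake <- simulate_hand_trajectory(sim_config(tremor_frequency = 6,
                                               amplitude_start = 10))
  imu2 <- synthesize_imu(shake, noise_sd = 0)
  az <- imu2$accel[, 3L] - 9.81
  expect_equal(diff(range(az)) / 2, 0.01 * (2 * pi * 6)^2, tolerance = 0.03)

  # and its band-passed spectrum peaks at the tremor frequency
  pk <- imu_peak_frequency(imu2)
  expect_equal(pk$peak_frequency, 6, tolerance = pk$bin_width + 1e-9)
})

test_that("noiseless world displacement concentrates at the tremor line", {
  tr <- simulate_hand_trajectory(sim_config(tremor_frequency = 6))
  x <- bandpass(landmark_positions(tr, 12, 3), 120)
  spec <- welch_spectrum(x, 120)
  expect_equal(spec$frequencies[which.max(spec$power[, 1L])], 6,
               tolerance = diff(spec$frequencies[1:2]) + 1e-9)
})

test_that("cohort sampling is positive, monotone in TETRAS, and reproducible", {
  co <- synthesize_cohort(n_subjects = 6, seed = 3L, duration = 2)
  expect_equal(nrow(co$subjects), 6L)
  expect_true(all(co$subjects$true_swing_amplitude_mm > 0))
  ord <- order(co$subjects$true_swing_amplitude_mm)
  expect_true(all(diff(co$subjects$tetras_score[ord]) >= 0))
  co2 <- synthesize_cohort(n_subjects = 6, seed = 3L, duration = 2)
  expect_identical(co$subjects, co2$subjects)
  expect_error(synthesize_cohort(amplitude_range_mm = c(-1, 5)),
               class = "tremorcv_error_config")
})

test_that("TETRAS map scores amplitudes by its thresholds", {
  expect_equal(tetras_score(0.5), 0)
  expect_equal(tetras_score(1), 0.5)        # within band 1, below its midpoint
  expect_equal(tetras_score(5), 1)
  expect_equal(tetras_score(250), 4.5)
  expect_equal(tetras_score(500), 5)
  amps <- exp(seq(log(0.2), log(400), length.out = 60))
  expect_true(all(diff(tetras_score(amps)) >= 0))
})
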