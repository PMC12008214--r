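# Synthetic tremulous-hand generator: rigid 21-landmark hand, pinhole camera,
# tracker-like noise, co-registered OMC-like and IMU-like ground truth.

#' Simulate the noiseless 3D hand trajectory
#'
#' The 21-landmark splayed-hand template translates rigidly along the world
#' image of `tremor_axis` with displacement
#' `envelope(t) * sin(phase(t))`, where the envelope interpolates linearly from
#' `amplitude_start` to `amplitude_end` (optionally modulated cycle-by-cycle)
#' and the phase accumulates `2 pi f_c dt` with a per-cycle frequency `f_c`
#' (optionally jittered). Articulated finger motion is not modeled: the
#' analysis pipeline reads only landmark 12, so rigid translation carries all
#' the information the pipeline consumes.
#'
#' @param config A [sim_config()].
#' @return A `trajectory_trace` in `"world_mm"` space (all frames detected,
#'   confidence 1) with attributes `envelope_mm` (the noiseless linear
#'   half-amplitude envelope per frame), `scene_center_mm`, `palm_normal` and
#'   `config`.
#' @export
simulate_hand_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate
  n <- max(2L, round(config$duration * fs))
  t <- (seq_len(n) - 1L) / fs
  envelope <- seq(config$amplitude_start, config$amplitude_end, length.out = n)

  max_cycles <- ceiling(config$tremor_frequency * config$duration * 2) + 10L
  jitter <- with_seed(config$seed, list(
    freq = pmax(0.1, config$tremor_frequency +
                  stats::rnorm(max_cycles, 0, config$frequency_jitter_sd)),
    amp = pmax(0, 1 + stats::rnorm(max_cycles, 0, config$amplitude_noise_cv))
  ))

  if (config$frequency_jitter_sd == 0 && config$amplitude_noise_cv == 0) {
    phase <- 2 * pi * config$tremor_frequency * t
    disp <- envelope * sin(phase)
  } else {
    phase <- numeric(n)
    for (k in seq_len(n - 1L)) {
      cyc <- min(max_cycles, floor(phase[k] / (2 * pi)) + 1L)
      phase[k + 1L] <- phase[k] + 2 * pi * jitter$freq[cyc] / fs
    }
    cyc_idx <- pmin(max_cycles, floor(phase / (2 * pi)) + 1L)
    disp <- envelope * jitter$amp[cyc_idx] * sin(phase)
  }

  basis <- hand_basis(config$palm_normal)
  axis_world <- as.vector(basis %*% config$tremor_axis)
  template_world <- sweep(hand_template() %*% t(basis), 2L,
                          config$wrist_position * 1000, `+`)

  pos <- array(NA_real_, dim = c(n, 21L, 3L))
  for (ax in 1:3) {
    pos[, , ax] <- outer(disp * axis_world[ax], rep(1, 21)) +
      matrix(template_world[, ax], n, 21L, byrow = TRUE)
  }

  trace <- trajectory_trace(t, pos, "world_mm", landmark_ids = 0:20,
                            sample_rate = fs)
  attr(trace, "envelope_mm") <- seq(config$amplitude_start,
                                    config$amplitude_end, length.out = n)
  attr(trace, "scene_center_mm") <- colMeans(template_world)
  attr(trace, "palm_normal") <- config$palm_normal
  attr(trace, "config") <- config
  trace
}

# camera-frame coordinates (right, up, depth), mm, for every frame x landmark
camera_frame_coords <- function(world_trace, camera) {
  stopifnot(inherits(world_trace, "trajectory_trace"),
            world_trace$space == "world_mm",
            inherits(camera, "camera_model"))
  center <- attr(world_trace, "scene_center_mm") %||%
    apply(world_trace$positions, 3L, mean, na.rm = TRUE)
  geo <- camera_geometry(camera, center / 1000)
  cam_pos_mm <- geo$position * 1000
  n <- n_frames(world_trace)
  nl <- length(world_trace$landmark_ids)
  flat <- matrix(world_trace$positions, nrow = n * nl, ncol = 3L)
  rel <- sweep(flat, 2L, cam_pos_mm)
  basis <- cbind(geo$right, geo$up, geo$forward)
  cam <- rel %*% basis
  list(x = matrix(cam[, 1L], n, nl), y = matrix(cam[, 2L], n, nl),
       depth = matrix(cam[, 3L], n, nl), geometry = geo, center_mm = center)
}

#' Project a world trace through a pinhole camera
#'
#' Standard pinhole projection after placing the camera on the viewpoint sphere
#' (see [camera_model()]); the image origin is top-left with y increasing
#' downward. The per-frame projected size (px) of a virtual 9.5 mm marker at
#' the fingertip is attached for scale-calibration tests, along with the
#' per-landmark camera depth used to emulate tracker depth channels.
#'
#' @param world_trace A `trajectory_trace` in `"world_mm"` space.
#' @param camera A [camera_model()].
#' @return A `trajectory_trace` in `"pixel"` space with attributes
#'   `marker_extent_px` (frames x 2), `camera_depth_mm`, `focal_length_px` and
#'   `camera`.
#' @export
project_to_camera <- function(world_trace, camera) {
  cc <- camera_frame_coords(world_trace, camera)
  if (any(cc$depth <= 0, na.rm = TRUE)) {
    bad <- which(rowSums(cc$depth <= 0, na.rm = TRUE) > 0)[1L]
    tremor_stop(sprintf("point behind camera at frame %d", bad),
                "tremorcv_error_projection")
  }
  f <- camera$focal_length
  u <- camera$principal_point[1L] + f * cc$x / cc$depth
  v <- camera$principal_point[2L] - f * cc$y / cc$depth
  n <- n_frames(world_trace)
  nl <- length(world_trace$landmark_ids)
  pos <- array(NA_real_, dim = c(n, nl, 2L))
  pos[, , 1L] <- u
  pos[, , 2L] <- v
  trace <- trajectory_trace(world_trace$timestamps, pos, "pixel",
                            landmark_ids = world_trace$landmark_ids,
                            confidence = world_trace$confidence,
                            detected = world_trace$detected,
                            sample_rate = world_trace$sample_rate,
                            frame_resolution = camera$resolution)
  tip <- match(FINGERTIP_LANDMARK, world_trace$landmark_ids)
  if (!is.na(tip)) {
    ext <- f * MARKER_DIAMETER_MM / cc$depth[, tip]
    attr(trace, "marker_extent_px") <- cbind(x = ext, y = ext)
  }
  attr(trace, "camera_depth_mm") <- cc$depth
  attr(trace, "focal_length_px") <- f
  attr(trace, "camera") <- camera
  attr(trace, "scene_center_mm") <- cc$center_mm
  attr(trace, "palm_normal") <- attr(world_trace, "palm_normal")
  trace
}

#' Apply tracker-like confidence, dropouts and localization jitter
#'
#' Per-frame confidence follows the view-dependence model of [noise_model()]:
#' it is highest for palm-on views and decays as the viewing direction turns
#' into the palm plane (frontal views), the pattern learned hand trackers
#' exhibit. Frames below the dropout threshold lose their positions; detected
#' positions receive additive Gaussian jitter (inflated on depth channels).
#' Deterministic given the noise seed.
#'
#' @param trace A `trajectory_trace` in pixel, normalized or metric space.
#' @param noise A [noise_model()].
#' @param camera A [camera_model()] (defines the viewing direction).
#' @param palm_normal World palm normal; defaults to the trace's attribute.
#' @return The trace with updated `confidence`, `detected` and jittered
#'   positions.
#' @export
apply_tracking_noise <- function(trace, noise, camera,
                                 palm_normal = attr(trace, "palm_normal")) {
  stopifnot(inherits(trace, "trajectory_trace"), inherits(noise, "noise_model"),
            inherits(camera, "camera_model"))
  palm_normal <- palm_normal %||% c(0, 0, 1)
  az <- camera$azimuth * pi / 180
  el <- camera$elevation * pi / 180
  view_dir <- c(sin(az) * cos(el), cos(az) * cos(el), -sin(el))
  cos_theta <- abs(sum(unitize(palm_normal) * view_dir))
  base_conf <- if (noise$confidence_view_exponent == 0) noise$confidence_base
               else noise$confidence_base *
                    cos_theta^noise$confidence_view_exponent

  n <- n_frames(trace)
  nl <- length(trace$landmark_ids)
  nax <- n_axes(trace)
  sds <- switch(trace$space,
    pixel = rep(noise$jitter_sd_px, nax),
    normalized = {
      res <- trace$frame_resolution
      c(noise$jitter_sd_px / res[1L], noise$jitter_sd_px / res[2L],
        noise$jitter_sd_px * noise$depth_noise_factor / res[1L])[seq_len(nax)]
    },
    world_mm = c(noise$jitter_sd_mm, noise$jitter_sd_mm,
                 noise$jitter_sd_mm * noise$depth_noise_factor)[seq_len(nax)],
    world_m = c(noise$jitter_sd_mm, noise$jitter_sd_mm,
                noise$jitter_sd_mm * noise$depth_noise_factor)[seq_len(nax)] / 1000)

  # AR(1) jitter with the configured correlation time and marginal SD
  phi <- if (noise$jitter_correlation_s > 0) {
    exp(-1 / (trace$sample_rate * noise$jitter_correlation_s))
  } else 0
  jitter_col <- function(n, sd) {
    if (sd == 0) return(numeric(n))
    e <- stats::rnorm(n)
    if (phi == 0) return(sd * e)
    sd * sqrt(1 - phi^2) *
      as.numeric(stats::filter(e, phi, method = "recursive"))
  }
  out <- with_seed(noise$seed, {
    conf <- base_conf + stats::rnorm(n, 0, noise$confidence_noise_sd)
    conf <- pmin(pmax(conf, 0), 1)
    detected <- conf >= noise$dropout_threshold
    pos <- trace$positions
    for (ax in seq_len(nax)) {
      for (j in seq_len(nl)) {
        pos[, j, ax] <- pos[, j, ax] + jitter_col(n, sds[ax])
      }
    }
    pos[!detected, , ] <- NA_real_
    list(conf = conf, detected = detected, pos = pos)
  })

  new_trace <- trajectory_trace(trace$timestamps, out$pos, trace$space,
                                landmark_ids = trace$landmark_ids,
                                confidence = out$conf, detected = out$detected,
                                sample_rate = trace$sample_rate,
                                frame_resolution = trace$frame_resolution)
  for (a in c("marker_extent_px", "camera_depth_mm", "focal_length_px",
              "camera", "scene_center_mm", "palm_normal")) {
    attr(new_trace, a) <- attr(trace, a)
  }
  new_trace
}

# spline-resample a trace to a new uniform rate (used for OMC/IMU emulation)
resample_trace <- function(trace, rate) {
  t_new <- seq(trace$timestamps[1L],
               trace$timestamps[length(trace$timestamps)], by = 1 / rate)
  nl <- length(trace$landmark_ids)
  nax <- n_axes(trace)
  pos <- array(NA_real_, dim = c(length(t_new), nl, nax))
  for (j in seq_len(nl)) {
    for (ax in seq_len(nax)) {
      pos[, j, ax] <- stats::spline(trace$timestamps, trace$positions[, j, ax],
                                    xout = t_new)$y
    }
  }
  trajectory_trace(t_new, pos, trace$space, landmark_ids = trace$landmark_ids,
                   sample_rate = rate,
                   frame_resolution = trace$frame_resolution)
}

#' Synthesize a tri-axial accelerometer series
#'
#' Spline-resamples the palm position (landmark centroid, meters) to the IMU
#' rate, takes the second central finite difference, and adds a constant
#' gravity vector plus white noise — emulating an IMU taped to the palm.
#'
#' @param world_trace A `trajectory_trace` in `"world_mm"` space.
#' @param noise_sd White-noise SD (m/s^2).
#' @param seed RNG seed.
#' @param sample_rate IMU rate (Hz); default 200.
#' @param gravity Gravity vector (m/s^2) in world coordinates.
#' @return An `imu_series`: list with `timestamps`, `accel` (n x 3, m/s^2) and
#'   `sample_rate`.
#' @export
synthesize_imu <- function(world_trace, noise_sd = 0.05, seed = 1L,
                           sample_rate = 200, gravity = c(0, 0, 9.81)) {
  stopifnot(inherits(world_trace, "trajectory_trace"),
            world_trace$space == "world_mm")
  palm_m <- apply(world_trace$positions, c(1L, 3L), mean) / 1000
  t_new <- seq(world_trace$timestamps[1L],
               world_trace$timestamps[length(world_trace$timestamps)],
               by = 1 / sample_rate)
  dt <- 1 / sample_rate
  acc <- matrix(NA_real_, length(t_new), 3L)
  for (ax in 1:3) {
    p <- stats::spline(world_trace$timestamps, palm_m[, ax], xout = t_new)$y
    a <- c(NA, diff(p, differences = 2L), NA) / dt^2
    a[1L] <- a[2L]
    a[length(a)] <- a[length(a) - 1L]
    acc[, ax] <- a + gravity[ax]
  }
  if (noise_sd > 0) {
    acc <- acc + with_seed(seed, matrix(stats::rnorm(length(acc), 0, noise_sd),
                                        nrow = nrow(acc)))
  }
  structure(list(timestamps = t_new, accel = acc, sample_rate = sample_rate),
            class = "imu_series")
}

# MP-world-like trace: camera-frame metric coordinates centered on the hand,
# with slow multiplicative scale noise (the "2.5D" depth/scale uncertainty of
# image-based metric landmark estimates) and inflated depth jitter.
emulate_world_trace <- function(world_trace, camera, noise) {
  cc <- camera_frame_coords(world_trace, camera)
  n <- nrow(cc$x)
  nl <- ncol(cc$x)
  pos <- array(NA_real_, dim = c(n, nl, 3L))
  pos[, , 1L] <- cc$x
  pos[, , 2L] <- cc$y
  pos[, , 3L] <- cc$depth
  for (ax in 1:3) {
    pos[, , ax] <- sweep(pos[, , ax], 2L, colMeans(pos[, , ax]))
  }
  if (noise$scale_noise_cv > 0) {
    fs <- world_trace$sample_rate
    phi <- exp(-1 / (2 * fs))              # ~2 s correlation time
    scale <- with_seed(noise$seed + 17L, {
      u <- numeric(n)
      e <- stats::rnorm(n)
      u[1L] <- e[1L]
      for (k in 2:n) u[k] <- phi * u[k - 1L] + sqrt(1 - phi^2) * e[k]
      exp(noise$scale_noise_cv * u)
    })
    for (ax in 1:3) pos[, , ax] <- pos[, , ax] * scale
  }
  trace <- trajectory_trace(world_trace$timestamps, pos / 1000, "world_m",
                            landmark_ids = world_trace$landmark_ids,
                            sample_rate = world_trace$sample_rate)
  attr(trace, "palm_normal") <- attr(world_trace, "palm_normal")
  trace
}

#' Synthesize a complete co-registered scene
#'
#' One virtual recording: the noiseless world trajectory, an OMC-like trace
#' (three markers — thumb tip, middle MCP, middle fingertip — at the motion
#' capture rate with sub-millimeter noise), tracker-like traces for the three
#' video methods (metric world landmarks, frame-normalized landmarks with a
#' pseudo-depth channel, and pixel landmarks), and an IMU-like acceleration
#' series. All traces share the scene's time origin.
#'
#' @param config A [sim_config()].
#' @param camera A [camera_model()].
#' @param noise A [noise_model()].
#' @param omc_rate OMC sample rate (Hz); default 100.
#' @param omc_noise_sd_mm OMC marker noise SD (mm); default 0.1.
#' @param imu_noise_sd IMU white-noise SD (m/s^2); default 0.05.
#' @return A `synthetic_scene` list with elements `world`, `omc`, `mp_world`,
#'   `mp_norm`, `vi_pixel`, `imu`, `true_envelope_mm`,
#'   `true_swing_amplitude_mm` (= 2 x mean envelope), `config`, `camera`,
#'   `noise`.
#' @export
synthesize_scene <- function(config = sim_config(), camera = camera_model(),
                             noise = noise_model(), omc_rate = 100,
                             omc_noise_sd_mm = 0.1, imu_noise_sd = 0.05) {
  world <- simulate_hand_trajectory(config)

  omc <- resample_trace(
    trajectory_trace(world$timestamps,
                     world$positions[, match(c(4L, 9L, 12L), world$landmark_ids), ,
                                     drop = FALSE],
                     "world_mm", landmark_ids = c(4L, 9L, 12L),
                     sample_rate = world$sample_rate),
    omc_rate)
  if (omc_noise_sd_mm > 0) {
    omc$positions <- omc$positions +
      with_seed(noise$seed + 3L,
                array(stats::rnorm(length(omc$positions), 0, omc_noise_sd_mm),
                      dim = dim(omc$positions)))
  }

  pixel <- project_to_camera(world, camera)
  vi_noise <- noise
  vi_noise$seed <- noise$seed + 1L
  vi_pixel <- apply_tracking_noise(pixel, vi_noise, camera)

  mp_norm <- apply_tracking_noise(normalize_to_frame(pixel), noise, camera)

  mp_world_noise <- noise
  mp_world_noise$seed <- noise$seed + 2L
  mp_world <- apply_tracking_noise(emulate_world_trace(world, camera, noise),
                                   mp_world_noise, camera)

  imu <- synthesize_imu(world, noise_sd = imu_noise_sd, seed = noise$seed + 4L)

  env <- attr(world, "envelope_mm")
  structure(list(world = world, omc = omc, mp_world = mp_world,
                 mp_norm = mp_norm, vi_pixel = vi_pixel, imu = imu,
                 true_envelope_mm = env,
                 true_swing_amplitude_mm = 2 * mean(env),
                 config = config, camera = camera, noise = noise),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> f=%.3g Hz, envelope %.3g->%.3g mm, %d s @ %g Hz\n",
    x$config$tremor_frequency, x$config$amplitude_start, x$config$amplitude_end,
    round(x$config$duration), x$config$sample_rate))
  cat(sprintf("  camera az=%g el=%g, detected (norm trace) %d/%d frames\n",
              x$camera$azimuth, x$camera$elevation,
              sum(x$mp_norm$detected), length(x$mp_norm$detected)))
  invisible(x)
}

#' Synthesize a cohort of virtual tremor subjects
#'
#' Draws per-subject tremor swing amplitudes log-uniformly and frequencies
#' uniformly from the given ranges, simulates one scene per subject under a
#' common camera/noise setup, and assigns each an ordinal TETRAS-like score
#' from its true swing amplitude via a monotone threshold map.
#'
#' @param n_subjects Number of subjects (>= 1); default 20.
#' @param amplitude_range_mm Range of the true swing (peak-to-peak path)
#'   amplitude in mm, sampled log-uniformly; default 1-100 mm.
#' @param frequency_range_hz Range of tremor frequencies, sampled uniformly;
#'   default 3.5-7.5 Hz.
#' @param tetras_map Threshold map, see [default_tetras_map()].
#' @param seed Integer seed; the cohort is deterministic given it.
#' @param camera,noise Shared [camera_model()] / [noise_model()].
#' @param duration,sample_rate Recording length (s) and video rate (Hz).
#' @return A `synthetic_cohort`: list with `subjects` (data.frame: `subject_id`,
#'   `true_swing_amplitude_mm`, `frequency_hz`, `tetras_score`) and `scenes`
#'   (list of `synthetic_scene`).
#' @export
synthesize_cohort <- function(n_subjects = 20,
                              amplitude_range_mm = c(1, 100),
                              frequency_range_hz = c(3.5, 7.5),
                              tetras_map = default_tetras_map(),
                              seed = 1L,
                              camera = camera_model(),
                              noise = noise_model(),
                              duration = 30, sample_rate = 120) {
  if (n_subjects < 1) tremor_stop("n_subjects must be >= 1",
                                  "tremorcv_error_config")
  if (diff(amplitude_range_mm) < 0 || any(amplitude_range_mm <= 0)) {
    tremor_stop("amplitude_range_mm must be positive and non-empty",
                "tremorcv_error_config")
  }
  if (diff(frequency_range_hz) < 0 || any(frequency_range_hz <= 0)) {
    tremor_stop("frequency_range_hz must be positive and non-empty",
                "tremorcv_error_config")
  }
  draws <- with_seed(seed, list(
    amp = exp(stats::runif(n_subjects, log(amplitude_range_mm[1L]),
                           log(amplitude_range_mm[2L]))),
    freq = stats::runif(n_subjects, frequency_range_hz[1L],
                        frequency_range_hz[2L])
  ))
  scenes <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- sim_config(tremor_frequency = draws$freq[i],
                      amplitude_start = draws$amp[i] / 2,
                      duration = duration, sample_rate = sample_rate,
                      seed = seed + i * 101L)
    noise_i <- noise
    noise_i$seed <- seed + i * 7919L
    scenes[[i]] <- synthesize_scene(cfg, camera, noise_i)
  }
  subjects <- data.frame(
    subject_id = seq_len(n_subjects),
    true_swing_amplitude_mm = draws$amp,
    frequency_hz = draws$freq,
    tetras_score = tetras_score(draws$amp, tetras_map))
  structure(list(subjects = subjects, scenes = scenes, seed = seed),
            class = "synthetic_cohort")
}
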