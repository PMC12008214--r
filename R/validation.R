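# Method-agreement statistics and the two virtual experiments
# (camera-angle sweep, increasing-amplitude run) plus a synthetic cohort run.

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation with a two-sided p-value from the
#' tie-adjusted normal approximation. Being rank-based, tau is invariant under
#' strictly monotone transforms of either argument, so log-transforming
#' amplitudes for display never changes it.
#'
#' @param x,y Equal-length finite numeric vectors, length >= 3.
#' @return List with `tau` and `p_value`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    tremor_stop("x and y must have equal length >= 3", "tremorcv_error_input")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    tremor_stop("x and y must be finite", "tremorcv_error_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    tremor_stop("tau is undefined for an all-tied input",
                "tremorcv_error_degenerate")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p_value = unname(ct$p.value))
}

#' Amplitude estimation error metrics
#'
#' Per-subject absolute error (mm), relative error (% of ground truth) and
#' natural-log amplitudes, with group medians and IQRs. Missing estimates
#' (not-estimable recordings) are carried as `NA` and excluded from the
#' summaries.
#'
#' @param estimates Estimated amplitudes (mm), `NA` allowed.
#' @param truth Ground-truth amplitudes (mm), strictly positive.
#' @return List with `table` (per-subject data.frame) and the summary fields
#'   `median_abs_error`, `iqr_abs_error`, `median_rel_error_pct`,
#'   `iqr_rel_error_pct`, `n`, `n_missing`.
#' @export
amplitude_error_metrics <- function(estimates, truth) {
  if (length(estimates) != length(truth)) {
    tremor_stop("estimates and truth must be paired", "tremorcv_error_input")
  }
  if (any(!is.finite(truth)) || any(truth <= 0)) {
    tremor_stop("truth must be finite and strictly positive",
                "tremorcv_error_input")
  }
  abs_error <- abs(estimates - truth)
  rel_error_pct <- 100 * abs_error / truth
  tab <- data.frame(estimate = estimates, truth = truth,
                    abs_error = abs_error, rel_error_pct = rel_error_pct,
                    log_estimate = ifelse(is.finite(estimates) & estimates > 0,
                                          log(estimates), NA_real_),
                    log_truth = log(truth))
  iqr <- function(v) unname(diff(stats::quantile(v, c(0.25, 0.75), na.rm = TRUE)))
  list(table = tab,
       median_abs_error = stats::median(abs_error, na.rm = TRUE),
       iqr_abs_error = iqr(abs_error),
       median_rel_error_pct = stats::median(rel_error_pct, na.rm = TRUE),
       iqr_rel_error_pct = iqr(rel_error_pct),
       n = sum(is.finite(abs_error)), n_missing = sum(!is.finite(abs_error)))
}

#' Test for a systematic (amplitude-dependent) estimation error
#'
#' Kendall correlation between the ground-truth amplitude and the estimation
#' error: a significant positive correlation means the error grows with the
#' tremor itself — a systematic, not random, error.
#'
#' @param truth Ground-truth amplitudes.
#' @param errors Per-subject estimation errors.
#' @param alpha Significance level; default 0.05 (two-sided).
#' @return List with `tau`, `p_value`, `significant`.
#' @export
systematic_error_test <- function(truth, errors, alpha = 0.05) {
  kt <- kendall_tau(truth, errors)
  c(kt, list(significant = kt$p_value < alpha))
}

#' Compare paired method measurements across groups
#'
#' Two paired groups: a Shapiro-Wilk screen on the paired differences (alpha
#' 0.05) selects the paired t-test when normality is tenable and the Wilcoxon
#' signed-rank test otherwise. More than two groups: per-group Shapiro screens
#' select one-way ANOVA vs the Kruskal-Wallis test. The report names the test
#' used.
#'
#' @param samples_by_method Named list of numeric vectors, one per method.
#' @param paired Treat two-group input as paired by subject (default).
#' @param alpha Normality-screen level.
#' @return List with `method`, `statistic`, `p_value`.
#' @export
group_compare <- function(samples_by_method, paired = TRUE, alpha = 0.05) {
  if (!is.list(samples_by_method) || length(samples_by_method) < 2L) {
    tremor_stop("need at least 2 groups", "tremorcv_error_input")
  }
  ns <- lengths(samples_by_method)
  if (any(ns < 3L)) {
    tremor_stop("too few subjects per group (need >= 3)",
                "tremorcv_error_too_few_subjects")
  }
  if (length(samples_by_method) == 2L) {
    x <- samples_by_method[[1L]]
    y <- samples_by_method[[2L]]
    if (paired && length(x) != length(y)) {
      tremor_stop("paired groups must have equal length",
                  "tremorcv_error_unequal_pairing")
    }
    d <- x - y
    if (all(d == 0)) {
      return(list(method = "degenerate (identical groups)",
                  statistic = 0, p_value = 1))
    }
    normal <- tryCatch(stats::shapiro.test(d)$p.value > alpha,
                       error = function(e) FALSE)
    if (normal) {
      tt <- stats::t.test(x, y, paired = TRUE)
      list(method = "paired t-test", statistic = unname(tt$statistic),
           p_value = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      list(method = "Wilcoxon signed-rank", statistic = unname(wt$statistic),
           p_value = wt$p.value)
    }
  } else {
    vals <- unlist(samples_by_method, use.names = FALSE)
    grp <- factor(rep(names(samples_by_method) %||%
                        seq_along(samples_by_method), ns))
    normal <- all(vapply(samples_by_method, function(v) {
      tryCatch(stats::shapiro.test(v)$p.value > alpha,
               error = function(e) FALSE)
    }, logical(1)))
    if (normal) {
      fit <- stats::aov(vals ~ grp)
      s <- summary(fit)[[1L]]
      list(method = "one-way ANOVA", statistic = s[["F value"]][1L],
           p_value = s[["Pr(>F)"]][1L])
    } else {
      kt <- stats::kruskal.test(vals, grp)
      list(method = "Kruskal-Wallis", statistic = unname(kt$statistic),
           p_value = kt$p.value)
    }
  }
}

# build the per-method trace of a scene for a given variant
scene_trace <- function(scene, variant) {
  scene[[variant_info(variant)$trace]]
}

# marker calibration from the scene's projected fiducial extent
scene_calibration <- function(trace) {
  ext <- attr(trace, "marker_extent_px")
  if (is.null(ext)) return(NULL)
  calibrate_scale(colMeans(ext, na.rm = TRUE))
}

#' Camera-angle sweep over the viewpoint half-sphere
#'
#' Re-runs the simulated recording from every viewpoint of a half-sphere grid
#' (default azimuth -90..90, elevation -90..0, 15 degree steps), measuring
#' per-cell mean detection accuracy (per-frame confidence, undetected frames
#' scored 0) and, where estimable, the median swing amplitude of the chosen
#' method variant in its native units. Cells with too many dropouts report an
#' absent amplitude. Deterministic given the noise seed.
#'
#' @param config A [sim_config()].
#' @param noise A [noise_model()]; each cell derives its own sub-seed.
#' @param camera Camera template (distance, intrinsics); azimuth/elevation are
#'   overridden per cell.
#' @param grid_step Grid step (degrees); default 15.
#' @param azimuths,elevations Grid axes (degrees).
#' @param variant Method variant analyzed per cell; default `"MP_NORM_XY"`.
#' @param min_detected_fraction Cells with fewer detected frames report no
#'   amplitude.
#' @return An `angle_sweep_result` data.frame with columns `azimuth`,
#'   `elevation`, `accuracy`, `detected_fraction`, `median_amplitude`,
#'   `log_amplitude`.
#' @export
run_angle_sweep <- function(config = sim_config(), noise = noise_model(),
                            camera = camera_model(), grid_step = 15,
                            azimuths = seq(-90, 90, by = grid_step),
                            elevations = seq(-90, 0, by = grid_step),
                            variant = "MP_NORM_XY",
                            min_detected_fraction = 0.5) {
  world <- simulate_hand_trajectory(config)
  info <- variant_info(variant)
  grid <- expand.grid(azimuth = azimuths, elevation = elevations)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cam <- camera
    cam$azimuth <- grid$azimuth[i]
    cam$elevation <- grid$elevation[i]
    cell_noise <- noise
    cell_noise$seed <- noise$seed + i * 131L
    trace <- switch(info$trace,
      mp_norm = apply_tracking_noise(
        normalize_to_frame(project_to_camera(world, cam)), cell_noise, cam),
      vi_pixel = apply_tracking_noise(project_to_camera(world, cam),
                                      cell_noise, cam),
      mp_world = apply_tracking_noise(emulate_world_trace(world, cam, cell_noise),
                                      cell_noise, cam),
      omc = stop("the angle sweep applies to camera-based variants"))
    accuracy <- mean(ifelse(trace$detected, trace$confidence, 0))
    det_frac <- mean(trace$detected)
    amp <- NA_real_
    if (det_frac >= min_detected_fraction) {
      sw <- estimate_amplitude(trace, variant)
      if (sw$estimable) amp <- sw$median_amplitude
    }
    out[[i]] <- data.frame(azimuth = grid$azimuth[i],
                           elevation = grid$elevation[i],
                           accuracy = accuracy, detected_fraction = det_frac,
                           median_amplitude = amp,
                           log_amplitude = ifelse(is.finite(amp) & amp > 0,
                                                  log(amp), NA_real_))
  }
  res <- do.call(rbind, out)
  class(res) <- c("angle_sweep_result", class(res))
  attr(res, "variant") <- variant
  res
}

#' Ramping-amplitude experiment
#'
#' Simulates a tremor with linearly increasing amplitude, runs the amplitude
#' pipeline for each method variant, z-scores the per-swing amplitude
#' sequences and scores their Kendall agreement with the true amplitude
#' envelope sampled at the swing times. Variants that include a depth channel
#' are expected to track the envelope less faithfully than their x/y
#' counterparts.
#'
#' @param config Ramp configuration (`amplitude_start < amplitude_end`); the
#'   default ramps 0 to 20 mm half-amplitude over 30 s at 6 Hz.
#' @param camera,noise Scene setup.
#' @param variants Method variants to score.
#' @return A `ramp_result`: list with `table` (variant, tau, p_value,
#'   n_swings) and `sequences` (per-variant swing times, z-scored amplitudes,
#'   true envelope at those times).
#' @export
run_ramp_experiment <- function(config = sim_config(amplitude_start = 0,
                                                    amplitude_end = 20),
                                camera = camera_model(),
                                noise = noise_model(),
                                variants = method_variants()) {
  scene <- synthesize_scene(config, camera, noise)
  env_t <- scene$world$timestamps
  env_true <- 2 * scene$true_envelope_mm   # swing (peak-to-peak) scale
  rows <- list()
  sequences <- list()
  for (v in variants) {
    trace <- scene_trace(scene, v)
    calib <- if (trace$space %in% c("pixel", "normalized")) {
      scene_calibration(trace)
    } else NULL
    sw <- estimate_amplitude(trace, v, calibration = calib)
    if (!sw$estimable || length(sw$swing_amplitudes) < 3L) {
      rows[[v]] <- data.frame(variant = v, tau = NA_real_, p_value = NA_real_,
                              n_swings = length(sw$swing_amplitudes))
      next
    }
    env_at <- stats::approx(env_t, env_true, xout = sw$swing_times, rule = 2)$y
    kt <- kendall_tau(sw$swing_amplitudes, env_at)
    z <- as.vector(scale(sw$swing_amplitudes))
    rows[[v]] <- data.frame(variant = v, tau = kt$tau, p_value = kt$p_value,
                            n_swings = length(z))
    sequences[[v]] <- data.frame(time = sw$swing_times, z_amplitude = z,
                                 true_envelope = env_at)
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 sequences = sequences, config = config),
            class = "ramp_result")
}

#' Synthetic-cohort experiment
#'
#' Simulates a cohort of virtual tremor subjects, runs the full amplitude and
#' frequency pipelines for every method variant, and computes the
#' method-agreement statistics: per-variant amplitude error metrics against
#' the OMC-like ground truth, peak-frequency errors against the true simulated
#' frequency, Kendall correlation of estimated log amplitude with the
#' TETRAS-like scores, and the systematic-error test.
#'
#' @inheritParams synthesize_cohort
#' @param variants Method variants to analyze.
#' @return A `cohort_result`: list with `records` (one row per subject),
#'   `stats` (named list of summary statistics) and `subjects` (the generator's
#'   ground-truth table).
#' @export
run_cohort_experiment <- function(n_subjects = 20,
                                  amplitude_range_mm = c(1, 100),
                                  frequency_range_hz = c(3.5, 7.5),
                                  seed = 1L,
                                  camera = camera_model(),
                                  noise = noise_model(),
                                  variants = c("MP_WORLD_XY", "MP_WORLD_XYZ",
                                               "MP_NORM_XY", "MP_NORM_XYZ",
                                               "VI_XY")) {
  cohort <- synthesize_cohort(n_subjects = n_subjects,
                              amplitude_range_mm = amplitude_range_mm,
                              frequency_range_hz = frequency_range_hz,
                              seed = seed, camera = camera, noise = noise)
  subjects <- cohort$subjects
  n <- nrow(subjects)
  rec <- data.frame(subject_id = subjects$subject_id,
                    tetras_score = subjects$tetras_score,
                    true_swing_amplitude_mm = subjects$true_swing_amplitude_mm,
                    true_frequency_hz = subjects$frequency_hz)
  rec$omc_amplitude_mm <- NA_real_
  for (v in variants) rec[[paste0("amp_", v)]] <- NA_real_
  for (v in c("MP_NORM_XY", "VI_XY", "OMC_XYZ")) {
    rec[[paste0("freq_", v)]] <- NA_real_
  }
  rec$freq_IMU <- NA_real_

  for (i in seq_len(n)) {
    scene <- cohort$scenes[[i]]
    omc <- estimate_amplitude(scene$omc, "OMC_XYZ")
    if (omc$estimable) rec$omc_amplitude_mm[i] <- omc$median_amplitude
    for (v in variants) {
      trace <- scene_trace(scene, v)
      calib <- if (trace$space %in% c("pixel", "normalized")) {
        scene_calibration(trace)
      } else NULL
      sw <- estimate_amplitude(trace, v, calibration = calib)
      if (sw$estimable) rec[[paste0("amp_", v)]][i] <- sw$median_amplitude
    }
    for (v in c("MP_NORM_XY", "VI_XY", "OMC_XYZ")) {
      pk <- estimate_peak_frequency(scene_trace(scene, v), v)
      rec[[paste0("freq_", v)]][i] <- pk$peak_frequency
    }
    rec$freq_IMU[i] <- imu_peak_frequency(scene$imu)$peak_frequency
  }

  stats_out <- list()
  for (v in c("MP_NORM_XY", "VI_XY", "OMC_XYZ", "IMU")) {
    col <- if (v == "IMU") "freq_IMU" else paste0("freq_", v)
    stats_out[[paste0("median_abs_freq_error_", v)]] <-
      stats::median(abs(rec[[col]] - rec$true_frequency_hz), na.rm = TRUE)
    stats_out[[paste0("n_freq_detected_", v)]] <- sum(is.finite(rec[[col]]))
  }
  truth <- rec$omc_amplitude_mm
  for (v in variants) {
    est <- rec[[paste0("amp_", v)]]
    ok <- is.finite(est) & is.finite(truth) & truth > 0
    if (sum(ok) >= 3L) {
      m <- amplitude_error_metrics(est[ok], truth[ok])
      stats_out[[paste0("median_abs_error_mm_", v)]] <- m$median_abs_error
      stats_out[[paste0("median_rel_error_pct_", v)]] <- m$median_rel_error_pct
      se <- tryCatch(systematic_error_test(truth[ok], abs(est - truth)[ok]),
                     tremorcv_error = function(e) NULL)
      if (!is.null(se)) {
        stats_out[[paste0("systematic_error_tau_", v)]] <- se$tau
        stats_out[[paste0("systematic_error_p_", v)]] <- se$p_value
      }
    }
    ok2 <- is.finite(est) & est > 0
    if (sum(ok2) >= 3L && stats::sd(rec$tetras_score[ok2]) > 0) {
      kt <- kendall_tau(log(est[ok2]), rec$tetras_score[ok2])
      stats_out[[paste0("tetras_tau_", v)]] <- kt$tau
      stats_out[[paste0("tetras_p_", v)]] <- kt$p_value
    }
  }
  ok3 <- is.finite(truth) & truth > 0 & stats::sd(subjects$tetras_score) > 0
  if (sum(ok3) >= 3L) {
    kt <- kendall_tau(log(truth[ok3]), subjects$tetras_score[ok3])
    stats_out$tetras_tau_OMC <- kt$tau
    stats_out$tetras_p_OMC <- kt$p_value
  }
  structure(list(records = rec, stats = stats_out, subjects = subjects,
                 seed = seed),
            class = "cohort_result")
}
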