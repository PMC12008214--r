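# Scene parameterization: tremor kinematics, pinhole camera, tracking noise.

#' Tremor simulation configuration
#'
#' Parameterizes a quasi-sinusoidal hand tremor: a rigid 21-landmark hand whose
#' fingertip oscillates along `tremor_axis` with a linearly interpolated
#' amplitude envelope. Amplitudes are half-amplitudes (mm): a constant
#' `amplitude_start = A` gives a peak-to-peak excursion of `2 A`, which is also
#' the per-swing path length the amplitude pipeline estimates.
#'
#' @param tremor_frequency Tremor frequency (Hz); must lie below the Nyquist
#'   frequency `sample_rate / 2`. Pathological hand tremor lives at 2-12 Hz.
#' @param amplitude_start,amplitude_end Envelope half-amplitude (mm) at the
#'   start and end of the recording; equal values give a constant-amplitude run.
#' @param duration Recording length (s); default 30, a standard clinical epoch.
#' @param sample_rate Video frame rate (Hz); default 120 (slow-motion capture).
#' @param tremor_axis Unit 3-vector, hand-local frame (x = finger direction,
#'   z = palm normal). The default (palm normal) models the up/down hand flap
#'   of postural tremor with the wrist supported.
#' @param palm_normal Unit 3-vector, world frame (z up). Default palm-up.
#' @param wrist_position Wrist position in world meters; default origin.
#' @param frequency_jitter_sd Cycle-to-cycle SD of the instantaneous frequency
#'   (Hz); 0 gives a deterministic tone.
#' @param amplitude_noise_cv Cycle-to-cycle coefficient of variation of the
#'   envelope; 0 gives the exact linear envelope.
#' @param seed Integer RNG seed for the jitter terms.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tremor_frequency = 6,
                       amplitude_start = 10,
                       amplitude_end = amplitude_start,
                       duration = 30,
                       sample_rate = 120,
                       tremor_axis = c(0, 0, 1),
                       palm_normal = c(0, 0, 1),
                       wrist_position = c(0, 0, 0),
                       frequency_jitter_sd = 0,
                       amplitude_noise_cv = 0,
                       seed = 1L) {
  assert_scalar_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  assert_scalar_number(tremor_frequency, "tremor_frequency",
                       lower = 0, upper = sample_rate / 2,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(amplitude_start, "amplitude_start", lower = 0)
  assert_scalar_number(amplitude_end, "amplitude_end", lower = 0)
  assert_scalar_number(duration, "duration", lower = 0, strict_lower = TRUE)
  assert_unit_vector(tremor_axis, "tremor_axis")
  assert_unit_vector(palm_normal, "palm_normal")
  if (length(wrist_position) != 3L || any(!is.finite(wrist_position))) {
    tremor_stop("wrist_position must be a finite 3-vector (m)",
                "tremorcv_error_config")
  }
  assert_scalar_number(frequency_jitter_sd, "frequency_jitter_sd", lower = 0)
  assert_scalar_number(amplitude_noise_cv, "amplitude_noise_cv", lower = 0)
  structure(list(
    tremor_frequency = tremor_frequency,
    amplitude_start = amplitude_start, amplitude_end = amplitude_end,
    duration = duration, sample_rate = sample_rate,
    tremor_axis = as.numeric(tremor_axis),
    palm_normal = as.numeric(palm_normal),
    wrist_position = as.numeric(wrist_position),
    frequency_jitter_sd = frequency_jitter_sd,
    amplitude_noise_cv = amplitude_noise_cv,
    seed = as.integer(seed)), class = "sim_config")
}

#' Pinhole camera on the viewpoint half-sphere
#'
#' The camera sits on a sphere of radius `distance` around the scene center and
#' looks at it. `azimuth` rotates around the vertical axis (0 = in front of the
#' fingers' +y side); `elevation` 0 is a frontal (horizontal) view and -90 a
#' top-down view, so the half-sphere grid of viewpoints is azimuth -90..90,
#' elevation -90..0 in 15 degree steps.
#'
#' @param azimuth,elevation Camera angles (degrees).
#' @param distance Camera-to-scene distance (m); default 1.5, a tripod at arm's
#'   length from a seated patient.
#' @param focal_length Focal length (px).
#' @param resolution Image width/height (px); default 1920 x 1080.
#' @param principal_point Principal point (px); default image center.
#' @return A `camera_model` list.
#' @export
camera_model <- function(azimuth = 0, elevation = -45, distance = 1.5,
                         focal_length = 1500,
                         resolution = c(1920, 1080),
                         principal_point = resolution / 2) {
  assert_scalar_number(azimuth, "azimuth")
  assert_scalar_number(elevation, "elevation")
  assert_scalar_number(distance, "distance", lower = 0, strict_lower = TRUE)
  assert_scalar_number(focal_length, "focal_length", lower = 0, strict_lower = TRUE)
  if (length(resolution) != 2L || any(!is.finite(resolution)) ||
      any(resolution <= 0)) {
    tremor_stop("resolution must be two positive numbers",
                "tremorcv_error_config")
  }
  if (length(principal_point) != 2L || any(!is.finite(principal_point))) {
    tremor_stop("principal_point must be two finite numbers",
                "tremorcv_error_config")
  }
  structure(list(azimuth = azimuth, elevation = elevation, distance = distance,
                 focal_length = focal_length,
                 resolution = as.numeric(resolution),
                 principal_point = as.numeric(principal_point)),
            class = "camera_model")
}

# camera position (m) relative to the scene center, and look-at basis
camera_geometry <- function(camera, center) {
  az <- camera$azimuth * pi / 180
  el <- camera$elevation * pi / 180
  v <- c(sin(az) * cos(el), cos(az) * cos(el), -sin(el))
  pos <- center + camera$distance * v
  fwd <- unitize(center - pos)
  up <- c(0, 0, 1)
  if (abs(sum(fwd * up)) > 0.999) up <- c(0, 1, 0)
  right <- unitize(cross3(fwd, up))
  cam_up <- cross3(right, fwd)
  list(position = pos, forward = fwd, right = right, up = cam_up)
}

#' Landmark-tracking noise model
#'
#' Emulates the error structure of learned hand trackers: per-frame detection
#' confidence that decays as the view turns from the palm normal toward an
#' in-plane (frontal) view, frame dropouts below a confidence threshold,
#' additive localization jitter, an inflated noise level on depth channels
#' (depth is the weak, "2.5D" direction of image-based trackers) and slow
#' multiplicative scale noise on metric world-landmark estimates.
#'
#' Per-frame confidence is
#' `clip(confidence_base * |cos(theta)|^confidence_view_exponent + e, 0, 1)`
#' with `theta` the angle between the palm normal and the viewing direction and
#' `e` Gaussian with SD `confidence_noise_sd`; frames below `dropout_threshold`
#' are flagged undetected and their positions dropped.
#'
#' @param jitter_sd_px Localization jitter marginal SD in the image plane (px).
#' @param jitter_sd_mm Localization jitter marginal SD for metric traces (mm).
#' @param jitter_correlation_s Correlation time (s) of the jitter, modeled as
#'   an AR(1) process: learned trackers smooth landmarks across frames, so
#'   their localization error is temporally correlated, not white. 0 gives
#'   white jitter.
#' @param confidence_base Confidence for a perfectly palm-on view, in \[0, 1\].
#' @param confidence_view_exponent Exponent of the `|cos theta|` decay; 0
#'   disables the view dependence.
#' @param confidence_noise_sd SD of the additive confidence noise.
#' @param dropout_threshold Frames with confidence below it are undetected.
#' @param depth_noise_factor Multiplier on the jitter SD for depth channels;
#'   default 10, an order of magnitude worse than in-plane localization.
#' @param scale_noise_cv Coefficient of variation of the slow multiplicative
#'   scale noise applied to metric world-landmark traces (default 10%).
#' @param seed Integer RNG seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(jitter_sd_px = 1,
                        jitter_sd_mm = 1,
                        jitter_correlation_s = 0.05,
                        confidence_base = 0.98,
                        confidence_view_exponent = 2,
                        confidence_noise_sd = 0.02,
                        dropout_threshold = 0.3,
                        depth_noise_factor = 10,
                        scale_noise_cv = 0.10,
                        seed = 1L) {
  assert_scalar_number(jitter_sd_px, "jitter_sd_px", lower = 0)
  assert_scalar_number(jitter_sd_mm, "jitter_sd_mm", lower = 0)
  assert_scalar_number(jitter_correlation_s, "jitter_correlation_s", lower = 0)
  assert_scalar_number(confidence_base, "confidence_base", lower = 0, upper = 1)
  assert_scalar_number(confidence_view_exponent, "confidence_view_exponent",
                       lower = 0)
  assert_scalar_number(confidence_noise_sd, "confidence_noise_sd", lower = 0)
  assert_scalar_number(dropout_threshold, "dropout_threshold",
                       lower = 0, upper = 1)
  assert_scalar_number(depth_noise_factor, "depth_noise_factor", lower = 0)
  assert_scalar_number(scale_noise_cv, "scale_noise_cv", lower = 0)
  structure(list(jitter_sd_px = jitter_sd_px, jitter_sd_mm = jitter_sd_mm,
                 jitter_correlation_s = jitter_correlation_s,
                 confidence_base = confidence_base,
                 confidence_view_exponent = confidence_view_exponent,
                 confidence_noise_sd = confidence_noise_sd,
                 dropout_threshold = dropout_threshold,
                 depth_noise_factor = depth_noise_factor,
                 scale_noise_cv = scale_noise_cv,
                 seed = as.integer(seed)), class = "noise_model")
}
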