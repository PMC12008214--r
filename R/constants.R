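# Package constants: hand-landmark template, method variants, TETRAS map.

#' 21-landmark splayed-hand template
#'
#' Hand-local coordinates in millimeters of the standard 21-point hand topology
#' (0 = wrist; 1-4 thumb; 5-8 index; 9-12 middle; 13-16 ring; 17-20 little
#' finger, base to tip). The local frame has x along the middle finger, y across
#' the palm (thumb side positive) and z along the palm normal. The template is a
#' plausible adult hand, splayed flat; the simulator moves it rigidly, since the
#' analysis pipeline only ever reads landmark 12 (middle fingertip).
#'
#' @return A 21 x 3 numeric matrix (mm), rownames `lm0` ... `lm20`.
#' @export
hand_template <- function() {
  m <- matrix(c(
      0,   0, 0,    # 0 wrist
     25,  35, 0,    # 1 thumb CMC
     55,  55, 5,    # 2 thumb MCP
     80,  70, 5,    # 3 thumb IP
    100,  82, 5,    # 4 thumb tip
     88,  28, 0,    # 5 index MCP
    123,  30, 2,    # 6 index PIP
    147,  31, 2,    # 7 index DIP
    166,  32, 2,    # 8 index tip
     92,   0, 0,    # 9 middle MCP
    130,   0, 2,    # 10 middle PIP
    157,   0, 2,    # 11 middle DIP
    180,   0, 2,    # 12 middle tip
     88, -26, 0,    # 13 ring MCP
    122, -28, 2,    # 14 ring PIP
    146, -29, 2,    # 15 ring DIP
    164, -30, 2,    # 16 ring tip
     80, -50, 0,    # 17 little MCP
    105, -55, 2,    # 18 little PIP
    122, -58, 2,    # 19 little DIP
    138, -60, 2     # 20 little tip
  ), ncol = 3, byrow = TRUE)
  dimnames(m) <- list(paste0("lm", 0:20), c("x", "y", "z"))
  m
}

# landmark id of the middle fingertip -- the only point the pipeline analyzes
FINGERTIP_LANDMARK <- 12L

# diameter of the optical motion-capture marker used for scale calibration (mm)
MARKER_DIAMETER_MM <- 9.5

#' Method variants
#'
#' The six trace/axis combinations compared by the pipeline: Mediapipe-style
#' world (metric) or normalized landmarks with or without the depth channel,
#' Vision-style pixel landmarks (x/y only), and optical motion capture (always
#' 3D). The variant fixes which synthetic-scene trace is read and which axes
#' enter the displacement computation; spectra for the video-based variants use
#' the x/y axes only (the depth channel adds noise to frequency estimation),
#' while OMC uses all three.
#'
#' @return Character vector of the six variant names.
#' @export
method_variants <- function() {
  names(.VARIANTS)
}

.VARIANTS <- list(
  MP_WORLD_XY  = list(trace = "mp_world", axes = 1:2, spectral_axes = 1:2),
  MP_WORLD_XYZ = list(trace = "mp_world", axes = 1:3, spectral_axes = 1:2),
  MP_NORM_XY   = list(trace = "mp_norm",  axes = 1:2, spectral_axes = 1:2),
  MP_NORM_XYZ  = list(trace = "mp_norm",  axes = 1:3, spectral_axes = 1:2),
  VI_XY        = list(trace = "vi_pixel", axes = 1:2, spectral_axes = 1:2),
  OMC_XYZ      = list(trace = "omc",      axes = 1:3, spectral_axes = 1:3)
)

variant_info <- function(variant) {
  variant <- match.arg(variant, names(.VARIANTS))
  c(list(name = variant), .VARIANTS[[variant]])
}

#' Default amplitude-to-TETRAS threshold map
#'
#' Ordinal tremor-severity scores (0-5 in half-point steps) assigned from the
#' tremor swing amplitude in millimeters. Full-point thresholds approximate the
#' published TETRAS performance-item amplitude anchors (1, 10, 30, 100 and
#' 200 mm); half-point scores sit at the geometric midpoints of each band,
#' reflecting the logarithmic perception of tremor severity (Weber-Fechner).
#' The map is configurable wherever it is consumed; these defaults are an
#' approximation, not a clinical instrument.
#'
#' @return A data.frame with columns `score` (0.5 ... 5) and `threshold_mm`,
#'   the smallest amplitude receiving that score.
#' @export
default_tetras_map <- function() {
  full <- c(1, 10, 30, 100, 200)
  upper <- c(full[-1], 400)
  thr <- as.vector(rbind(full, sqrt(full * upper)))
  data.frame(score = seq(0.5, 5, by = 0.5), threshold_mm = thr)
}

#' Map amplitudes to TETRAS-like ordinal scores
#'
#' @param amplitude_mm Numeric vector of tremor swing amplitudes (mm).
#' @param map Threshold map as returned by [default_tetras_map()].
#' @return Numeric vector of scores in 0-5 (half-point steps); monotone
#'   non-decreasing in amplitude.
#' @export
tetras_score <- function(amplitude_mm, map = default_tetras_map()) {
  if (!all(c("score", "threshold_mm") %in% names(map))) {
    tremor_stop("`map` needs columns score and threshold_mm",
                "tremorcv_error_config")
  }
  map <- map[order(map$threshold_mm), , drop = FALSE]
  vapply(amplitude_mm, function(a) {
    if (!is.finite(a) || a < 0) return(NA_real_)
    hit <- which(map$threshold_mm <= a)
    if (length(hit) == 0L) 0 else max(map$score[hit])
  }, numeric(1))
}
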