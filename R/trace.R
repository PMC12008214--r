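# TrajectoryTrace: the universal currency between pipeline stages.

#' Construct a landmark trajectory trace
#'
#' A `trajectory_trace` holds per-frame positions of up to 21 hand landmarks in
#' one of four coordinate spaces, together with per-frame detection confidence
#' and a detected flag. Undetected frames carry missing positions end-to-end;
#' they are never silently zero-filled.
#'
#' @param timestamps Strictly increasing frame times (s).
#' @param positions Numeric array `frames x landmarks x axes` (axes are x,y or
#'   x,y,z). Positions of undetected frames must be `NA`.
#' @param space One of `"world_mm"`, `"world_m"`, `"normalized"`, `"pixel"`.
#' @param landmark_ids Integer landmark ids (0-20, standard 21-point topology).
#' @param confidence Per-frame detection confidence in \[0, 1\].
#' @param detected Per-frame logical; defaults to all `TRUE`.
#' @param sample_rate Hz; inferred from the median timestamp spacing if `NULL`.
#' @param frame_resolution Width/height in px; required for `"normalized"` and
#'   `"pixel"` spaces.
#' @return An object of class `trajectory_trace`.
#' @export
trajectory_trace <- function(timestamps, positions, space,
                             landmark_ids = 0:20,
                             confidence = NULL, detected = NULL,
                             sample_rate = NULL, frame_resolution = NULL) {
  space <- match.arg(space, c("world_mm", "world_m", "normalized", "pixel"))
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  if (n < 1L || any(!is.finite(timestamps))) {
    tremor_stop("timestamps must be finite and non-empty",
                "tremorcv_error_timestamps")
  }
  if (n > 1L && any(diff(timestamps) <= 0)) {
    tremor_stop("timestamps must be strictly increasing",
                "tremorcv_error_timestamps")
  }
  if (length(dim(positions)) != 3L) {
    tremor_stop("positions must be a frames x landmarks x axes array",
                "tremorcv_error_positions")
  }
  if (dim(positions)[1L] != n) {
    tremor_stop("positions and timestamps disagree on frame count",
                "tremorcv_error_positions")
  }
  n_axes <- dim(positions)[3L]
  if (!n_axes %in% 2:3) {
    tremor_stop("positions must have 2 or 3 axes", "tremorcv_error_positions")
  }
  landmark_ids <- as.integer(landmark_ids)
  if (dim(positions)[2L] != length(landmark_ids) ||
      any(landmark_ids < 0L | landmark_ids > 20L)) {
    tremor_stop("landmark_ids must match positions and lie in 0-20",
                "tremorcv_error_positions")
  }
  confidence <- if (is.null(confidence)) rep(1, n) else as.numeric(confidence)
  detected <- if (is.null(detected)) rep(TRUE, n) else as.logical(detected)
  if (length(confidence) != n || any(confidence < -1e-9 | confidence > 1 + 1e-9,
                                     na.rm = TRUE)) {
    tremor_stop("confidence must be per-frame in [0, 1]",
                "tremorcv_error_confidence")
  }
  confidence <- pmin(pmax(confidence, 0), 1)
  if (length(detected) != n) {
    tremor_stop("detected must be per-frame", "tremorcv_error_confidence")
  }
  if (space %in% c("normalized", "pixel")) {
    if (is.null(frame_resolution) || length(frame_resolution) != 2L ||
        any(frame_resolution <= 0)) {
      tremor_stop("frame_resolution (width, height) > 0 is required for pixel/normalized spaces",
                  "tremorcv_error_config")
    }
  }
  det_pos <- positions[detected, , , drop = FALSE]
  if (any(!is.finite(det_pos))) {
    tremor_stop("positions of detected frames must be finite",
                "tremorcv_error_positions")
  }
  if (space == "normalized" && length(det_pos) &&
      any(det_pos[, , 1:2] < -0.5 | det_pos[, , 1:2] > 1.5, na.rm = TRUE)) {
    tremor_stop("normalized coordinates of detected frames must lie in [-0.5, 1.5]",
                "tremorcv_error_positions")
  }
  if (is.null(sample_rate)) {
    sample_rate <- if (n > 1L) 1 / stats::median(diff(timestamps)) else NA_real_
  }
  structure(
    list(timestamps = timestamps, positions = positions, space = space,
         landmark_ids = landmark_ids, confidence = confidence,
         detected = detected, sample_rate = as.numeric(sample_rate),
         frame_resolution = if (is.null(frame_resolution)) NULL
                            else as.numeric(frame_resolution)),
    class = "trajectory_trace")
}

#' @export
print.trajectory_trace <- function(x, ...) {
  cat(sprintf("<trajectory_trace> %d frames, %d landmarks, %d axes, space=%s\n",
              length(x$timestamps), length(x$landmark_ids),
              dim(x$positions)[3L], x$space))
  cat(sprintf("  sample_rate=%.6g Hz, detected %d/%d frames\n",
              x$sample_rate, sum(x$detected), length(x$detected)))
  invisible(x)
}

n_frames <- function(trace) length(trace$timestamps)

n_axes <- function(trace) dim(trace$positions)[3L]

#' Extract one landmark's positions as a matrix
#'
#' @param trace A `trajectory_trace`.
#' @param landmark Landmark id (default 12, the middle fingertip).
#' @param axes Integer axis indices to keep.
#' @return A `frames x length(axes)` matrix; undetected frames are `NA`.
#' @export
landmark_positions <- function(trace, landmark = FINGERTIP_LANDMARK,
                               axes = seq_len(n_axes(trace))) {
  j <- match(as.integer(landmark), trace$landmark_ids)
  if (is.na(j)) {
    tremor_stop(sprintf("landmark %d is not present in the trace", landmark),
                "tremorcv_error_landmark")
  }
  if (any(axes > n_axes(trace))) {
    tremor_stop("requested axes not available in this trace",
                "tremorcv_error_axes")
  }
  m <- trace$positions[, j, axes, drop = FALSE]
  dim(m) <- c(dim(trace$positions)[1L], length(axes))
  m
}

#' Normalize a pixel trace to frame-relative coordinates
#'
#' Divides x by the frame width and y by the frame height, the convention of
#' normalized-landmark hand trackers (origin top-left, y down). When the pixel
#' trace carries per-frame camera depth (as traces produced by
#' [project_to_camera()] do), a pseudo-depth channel scaled like x is appended,
#' emulating trackers whose depth estimate shares the x-axis scale.
#'
#' @param pixel_trace A `trajectory_trace` in `"pixel"` space.
#' @param resolution Width/height (px); defaults to the trace's resolution.
#' @return A `trajectory_trace` in `"normalized"` space.
#' @export
normalize_to_frame <- function(pixel_trace, resolution = NULL) {
  stopifnot(inherits(pixel_trace, "trajectory_trace"))
  if (pixel_trace$space != "pixel") {
    tremor_stop("normalize_to_frame expects a pixel-space trace",
                "tremorcv_error_space")
  }
  resolution <- resolution %||% pixel_trace$frame_resolution
  if (is.null(resolution) || any(resolution <= 0)) {
    tremor_stop("resolution (width, height) > 0 required",
                "tremorcv_error_config")
  }
  pos <- pixel_trace$positions
  out <- pos
  out[, , 1L] <- pos[, , 1L] / resolution[1L]
  out[, , 2L] <- pos[, , 2L] / resolution[2L]
  depth <- attr(pixel_trace, "camera_depth_mm")
  focal <- attr(pixel_trace, "focal_length_px")
  if (!is.null(depth) && !is.null(focal)) {
    # depth variation re-expressed on the x-axis scale: mm -> px at the mean
    # working distance, then / width like x
    z_px <- focal * sweep(depth, 2L, colMeans(depth, na.rm = TRUE)) /
      mean(depth, na.rm = TRUE)
    out2 <- array(NA_real_, dim = c(dim(pos)[1:2], 3L))
    out2[, , 1:2] <- out[, , 1:2]
    out2[, , 3L] <- z_px / resolution[1L]
    out <- out2
  }
  tr <- trajectory_trace(pixel_trace$timestamps, out, "normalized",
                         landmark_ids = pixel_trace$landmark_ids,
                         confidence = pixel_trace$confidence,
                         detected = pixel_trace$detected,
                         sample_rate = pixel_trace$sample_rate,
                         frame_resolution = resolution)
  attr(tr, "marker_extent_px") <- attr(pixel_trace, "marker_extent_px")
  tr
}

#' Invert frame normalization
#'
#' Exact inverse of [normalize_to_frame()] on the x/y channels (any pseudo-depth
#' channel is dropped, since it has no pixel-space counterpart).
#'
#' @param norm_trace A `trajectory_trace` in `"normalized"` space.
#' @param resolution Width/height (px); defaults to the trace's resolution.
#' @return A `trajectory_trace` in `"pixel"` space.
#' @export
denormalize_from_frame <- function(norm_trace, resolution = NULL) {
  stopifnot(inherits(norm_trace, "trajectory_trace"))
  if (norm_trace$space != "normalized") {
    tremor_stop("denormalize_from_frame expects a normalized-space trace",
                "tremorcv_error_space")
  }
  resolution <- resolution %||% norm_trace$frame_resolution
  if (is.null(resolution) || any(resolution <= 0)) {
    tremor_stop("resolution (width, height) > 0 required",
                "tremorcv_error_config")
  }
  pos <- norm_trace$positions[, , 1:2, drop = FALSE]
  pos[, , 1L] <- pos[, , 1L] * resolution[1L]
  pos[, , 2L] <- pos[, , 2L] * resolution[2L]
  trajectory_trace(norm_trace$timestamps, pos, "pixel",
                   landmark_ids = norm_trace$landmark_ids,
                   confidence = norm_trace$confidence,
                   detected = norm_trace$detected,
                   sample_rate = norm_trace$sample_rate,
                   frame_resolution = resolution)
}
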