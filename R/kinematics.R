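# Amplitude-estimation pipeline: displacement series, band-pass, turning
# points, per-swing amplitudes, median amplitude, pixel-to-mm calibration.
#
# Order of operations: the 2-10 Hz band-pass is applied to the per-axis
# POSITIONS. The displacement magnitude of an f-Hz tremor oscillates at 2f,
# which for f > 5 Hz would fall outside the band; filtering positions keeps a
# 6 Hz tremor (the canonical validation case) inside it. Turning points are
# detected on the filtered-position displacement; swing amplitudes sum the
# unfiltered-position displacement, so no path length is lost to filtering.

#' Zero-phase Butterworth band-pass
#'
#' 4th-order Butterworth applied forward and backward (zero phase, so turning
#' point timing is preserved), with odd-reflection edge padding to suppress
#' filter transients at the series ends. Removes DC and slow drift below the
#' low cutoff and tracking noise above the high cutoff.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param sample_rate Sampling rate (Hz).
#' @param low,high Band edges (Hz); defaults 2 and 10, bracketing the
#'   pathological tremor band while excluding voluntary movement and drift.
#' @param order Butterworth order per edge; default 4.
#' @return Filtered object of the same shape.
#' @export
bandpass <- function(x, sample_rate, low = 2, high = 10, order = 4) {
  if (!(0 < low && low < high && high < sample_rate / 2)) {
    tremor_stop("band must satisfy 0 < low < high < sample_rate/2",
                "tremorcv_error_band")
  }
  if (is.matrix(x)) {
    return(apply(x, 2L, bandpass, sample_rate = sample_rate, low = low,
                 high = high, order = order))
  }
  n <- length(x)
  min_n <- 3L * (2L * order + 1L)
  if (n < min_n) {
    tremor_stop(sprintf("series too short to band-pass (%d < %d samples)",
                        n, min_n), "tremorcv_error_too_short")
  }
  bf <- signal::butter(order, c(low, high) / (sample_rate / 2), type = "pass")
  mu <- mean(x)              # remove DC up front: the filter transient on a
  x <- x - mu                # large offset would otherwise leak past the pad
  pad <- min(n - 1L, ceiling(3 * sample_rate / low))
  head_ref <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  tail_ref <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(head_ref, x, tail_ref))
  y[seq(pad + 1L, pad + n)]
}

#' Pixel-to-millimeter scale calibration from a fiducial marker
#'
#' Converts the measured pixel extent of a marker of known physical diameter
#' (default: the 9.5 mm optical motion-capture marker taped to the fingertip)
#' into componentwise mm-per-px factors for the x and y image axes.
#'
#' @param marker_extent_px Marker extent in px: one value or an (x, y) pair.
#' @param marker_diameter_mm Physical marker diameter (mm); default 9.5.
#' @return A `scale_calibration` with `mm_per_px` (x, y pair).
#' @export
calibrate_scale <- function(marker_extent_px, marker_diameter_mm = MARKER_DIAMETER_MM) {
  if (length(marker_extent_px) == 1L) {
    marker_extent_px <- rep(marker_extent_px, 2L)
  }
  if (length(marker_extent_px) != 2L || any(!is.finite(marker_extent_px)) ||
      any(marker_extent_px <= 0)) {
    tremor_stop("marker_extent_px must be one or two positive numbers",
                "tremorcv_error_calibration")
  }
  assert_scalar_number(marker_diameter_mm, "marker_diameter_mm",
                       lower = 0, strict_lower = TRUE)
  structure(list(marker_diameter_mm = marker_diameter_mm,
                 marker_extent_px = as.numeric(marker_extent_px),
                 mm_per_px = marker_diameter_mm / as.numeric(marker_extent_px)),
            class = "scale_calibration")
}

# fingertip positions on the variant's axes, converted toward millimeters.
# Returns matrix + the units achieved ("mm" or the trace's native units).
fingertip_mm <- function(trace, variant, calibration = NULL) {
  info <- variant_info(variant)
  pos <- landmark_positions(trace, FINGERTIP_LANDMARK, axes = info$axes)
  units <- switch(trace$space,
    world_mm = "mm",
    world_m = "mm",
    pixel = if (is.null(calibration)) "px" else "mm",
    normalized = if (is.null(calibration)) "px" else "mm")
  if (trace$space == "world_m") pos <- pos * 1000
  if (trace$space == "normalized") {
    res <- trace$frame_resolution
    scale_px <- c(res[1L], res[2L], res[1L])[info$axes]
    pos <- sweep(pos, 2L, scale_px, `*`)
  }
  if (trace$space %in% c("pixel", "normalized") && !is.null(calibration)) {
    stopifnot(inherits(calibration, "scale_calibration"))
    # x scaled by the x factor, y by the y factor; pseudo-depth shares x scale
    fac <- c(calibration$mm_per_px, calibration$mm_per_px[1L])[info$axes]
    pos <- sweep(pos, 2L, fac, `*`)
  }
  list(pos = pos, units = units)
}

# split detected frames into contiguous segments, interpolating gaps of at
# most max_gap_s; longer gaps split the recording
segment_positions <- function(pos, detected, times, sample_rate,
                              max_gap_s = 0.25, min_seg = NULL) {
  ok <- detected & apply(is.finite(pos), 1L, all)
  n <- length(ok)
  min_seg <- min_seg %||% max(27L, round(0.5 * sample_rate))
  if (sum(ok) < 2L) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max_gap <- max_gap_s * sample_rate
  # frames belonging to long undetected runs split the trace
  long_gap <- !r$values & r$lengths > max_gap
  boundary <- rep(FALSE, n)
  for (k in which(long_gap)) boundary[starts[k]:ends[k]] <- TRUE
  seg_id <- cumsum(c(TRUE, diff(boundary) != 0))
  segments <- list()
  for (s in unique(seg_id[!boundary])) {
    idx <- which(seg_id == s & !boundary)
    sub_ok <- ok[idx]
    if (sum(sub_ok) < 2L) next
    # trim leading/trailing undetected frames, interpolate the short gaps
    first <- idx[which(sub_ok)[1L]]
    last <- idx[rev(which(sub_ok))[1L]]
    keep <- first:last
    p <- pos[keep, , drop = FALSE]
    p[!ok[keep], ] <- NA_real_
    p <- apply(p, 2L, interp_na)
    if (!is.matrix(p)) p <- matrix(p, ncol = ncol(pos))
    if (nrow(p) < min_seg || any(!is.finite(p))) next
    segments[[length(segments) + 1L]] <-
      list(times = times[keep], pos = p,
           interpolated = sum(!ok[keep]))
  }
  segments
}

#' Consecutive-frame displacement of the middle fingertip
#'
#' The Euclidean norm, over the variant's axes, of the fingertip position
#' difference between consecutive frames — the raw signal of the amplitude
#' pipeline. Undetected-frame gaps of at most `max_gap_s` are linearly
#' interpolated; longer gaps split the recording into segments that are
#' analyzed independently (interpolating across them would fabricate path
#' length). The `filtered` channel is the displacement of the band-passed
#' positions; `raw` comes from the unfiltered positions.
#'
#' @param trace A `trajectory_trace` containing landmark 12.
#' @param variant One of [method_variants()].
#' @param calibration Optional [calibrate_scale()] result for pixel/normalized
#'   traces.
#' @param band Band-pass edges (Hz).
#' @param max_gap_s Longest undetected gap (s) bridged by interpolation.
#' @return A `displacement_series`: `times` (frame-pair midpoints), `raw`,
#'   `filtered`, `segment` (integer id per sample), `sample_rate`, `variant`,
#'   `units`, `n_interpolated`.
#' @export
consecutive_displacement <- function(trace, variant, calibration = NULL,
                                     band = c(2, 10), max_gap_s = 0.25) {
  stopifnot(inherits(trace, "trajectory_trace"))
  ft <- fingertip_mm(trace, variant, calibration)
  if (sum(trace$detected) < 2L) {
    tremor_stop("fewer than 2 detected frames", "tremorcv_error_too_few_frames")
  }
  segs <- segment_positions(ft$pos, trace$detected, trace$timestamps,
                            trace$sample_rate, max_gap_s = max_gap_s)
  if (length(segs) == 0L) {
    tremor_stop("no analyzable segment after gap handling",
                "tremorcv_error_too_few_frames")
  }
  times <- raw <- filt <- numeric(0)
  seg_id <- integer(0)
  n_interp <- 0L
  for (s in seq_along(segs)) {
    p <- segs[[s]]$pos
    pf <- bandpass(p, trace$sample_rate, low = band[1L], high = band[2L])
    if (!is.matrix(pf)) pf <- matrix(pf, ncol = ncol(p))
    d_raw <- sqrt(rowSums(diff(p)^2))
    d_flt <- sqrt(rowSums(diff(pf)^2))
    tmid <- (segs[[s]]$times[-1L] + segs[[s]]$times[-length(segs[[s]]$times)]) / 2
    times <- c(times, tmid)
    raw <- c(raw, d_raw)
    filt <- c(filt, d_flt)
    seg_id <- c(seg_id, rep(s, length(d_raw)))
    n_interp <- n_interp + segs[[s]]$interpolated
  }
  structure(list(times = times, raw = raw, filtered = filt, segment = seg_id,
                 sample_rate = trace$sample_rate, variant = variant,
                 units = ft$units, band = band, n_interpolated = n_interp),
            class = "displacement_series")
}

#' Detect motion turning points
#'
#' Turning points are the strict local minima of the filtered displacement —
#' the instants where the fingertip reverses direction and the frame-to-frame
#' displacement is smallest. A minimum separation of
#' `sample_rate / (2 * high)` samples (half a cycle of the fastest passband
#' tremor) is enforced: an index qualifies only if its filtered displacement is
#' below every other value in that window (ties resolved to the earliest
#' index). Segment endpoints are excluded, and segments whose in-band motion is
#' negligible against their raw displacement (peak filtered displacement below
#' 5% of the median raw displacement, e.g. a monotone drift with no tremor)
#' yield no turning points at all. An empty result signals that no oscillation
#' is present and the amplitude is not estimable.
#'
#' @param displacement A `displacement_series`.
#' @param high High band edge (Hz) defining the minimum separation; defaults
#'   to the series' band.
#' @return Integer indices into the displacement series (possibly empty).
#' @export
detect_turning_points <- function(displacement,
                                  high = displacement$band[2L]) {
  stopifnot(inherits(displacement, "displacement_series"))
  w <- ceiling(displacement$sample_rate / (2 * high))
  out <- integer(0)
  for (s in unique(displacement$segment)) {
    idx <- which(displacement$segment == s)
    d <- displacement$filtered[idx]
    m <- length(d)
    if (m < 3L) next
    # no in-band oscillation (e.g. monotone drift): nothing to decompose
    if (max(d) <= 0.05 * stats::median(displacement$raw[idx])) next
    for (i in 2:(m - 1L)) {
      lo <- max(1L, i - w)
      hi <- min(m, i + w)
      left <- if (lo <= i - 1L) d[lo:(i - 1L)] else numeric(0)
      right <- if (i + 1L <= hi) d[(i + 1L):hi] else numeric(0)
      if ((length(left) == 0L || all(d[i] < left)) &&
          (length(right) == 0L || all(d[i] <= right))) {
        out <- c(out, idx[i])
      }
    }
  }
  out
}

#' Per-swing amplitudes and their median
#'
#' A swing is the motion between two consecutive turning points (within one
#' segment); its amplitude is the sum of the *unfiltered* displacement over the
#' half-open index interval between them — the path length traveled between
#' reversals. The recording's amplitude estimate is the median over swings
#' (even counts average the two central values), robust to occasional tracking
#' outliers.
#'
#' @param displacement A `displacement_series`.
#' @param turning_indices As returned by [detect_turning_points()].
#' @return A `swing_decomposition`: `turning_indices`, `swing_amplitudes`,
#'   `swing_times`, `median_amplitude`, `units`, `estimable`.
#' @export
swing_amplitudes <- function(displacement, turning_indices) {
  stopifnot(inherits(displacement, "displacement_series"))
  if (length(turning_indices) < 2L) {
    tremor_stop("insufficient oscillation: fewer than 2 turning points",
                "tremorcv_error_insufficient_oscillation")
  }
  turning_indices <- sort(as.integer(turning_indices))
  amps <- times <- numeric(0)
  for (k in seq_len(length(turning_indices) - 1L)) {
    a <- turning_indices[k]
    b <- turning_indices[k + 1L]
    if (displacement$segment[a] != displacement$segment[b]) next
    amps <- c(amps, sum(displacement$raw[a:(b - 1L)]))
    times <- c(times, (displacement$times[a] + displacement$times[b]) / 2)
  }
  if (length(amps) == 0L) {
    tremor_stop("insufficient oscillation: no within-segment swing",
                "tremorcv_error_insufficient_oscillation")
  }
  structure(list(turning_indices = turning_indices, swing_amplitudes = amps,
                 swing_times = times,
                 median_amplitude = stats::median(amps),
                 units = displacement$units, estimable = TRUE, reason = NULL),
            class = "swing_decomposition")
}

not_estimable <- function(reason, units = NA_character_) {
  structure(list(turning_indices = integer(0), swing_amplitudes = numeric(0),
                 swing_times = numeric(0), median_amplitude = NA_real_,
                 units = units, estimable = FALSE, reason = reason),
            class = "swing_decomposition")
}

#' @export
print.swing_decomposition <- function(x, ...) {
  if (x$estimable) {
    cat(sprintf("<swing_decomposition> %d swings, median amplitude %.4g %s\n",
                length(x$swing_amplitudes), x$median_amplitude, x$units))
  } else {
    cat(sprintf("<swing_decomposition> not estimable (%s)\n", x$reason))
  }
  invisible(x)
}

#' Estimate the tremor swing amplitude of a recording
#'
#' The full amplitude pipeline: fingertip displacement over the variant's axes
#' (with unit handling — metric traces to mm, pixel/normalized traces through
#' the marker calibration), 2-10 Hz zero-phase band-pass of the positions,
#' turning-point detection on the filtered displacement, per-swing path
#' lengths from the unfiltered displacement, and their median. When no
#' oscillation is detectable (for example when too many frames are undetected)
#' the result is flagged not estimable rather than raising an error.
#'
#' @inheritParams consecutive_displacement
#' @return A `swing_decomposition`; `median_amplitude` is `NA` and `estimable`
#'   `FALSE` when the amplitude cannot be estimated.
#' @export
estimate_amplitude <- function(trace, variant, calibration = NULL,
                               band = c(2, 10), max_gap_s = 0.25) {
  disp <- tryCatch(
    consecutive_displacement(trace, variant, calibration = calibration,
                             band = band, max_gap_s = max_gap_s),
    tremorcv_error_too_few_frames = function(e) e)
  if (inherits(disp, "condition")) {
    return(not_estimable(conditionMessage(disp)))
  }
  tp <- detect_turning_points(disp)
  if (length(tp) < 2L) {
    return(not_estimable("no turning points in band", disp$units))
  }
  sw <- tryCatch(swing_amplitudes(disp, tp),
                 tremorcv_error_insufficient_oscillation = function(e) e)
  if (inherits(sw, "condition")) {
    return(not_estimable(conditionMessage(sw), disp$units))
  }
  sw
}
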