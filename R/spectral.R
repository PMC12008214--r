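# Peak tremor-frequency estimation: Welch spectra with frequency-of-interest
# gating and a relative power threshold.

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-windowed, demeaned segments of
#' `segment_seconds` seconds with 50% overlap, zero-padded `zero_pad`-fold
#' before the FFT. Zero-padding interpolates the spectrum (frequency spacing
#' 0.025 Hz for 10 s segments padded 4x at any input rate), which the
#' sub-0.1 Hz frequency-error resolution of tremor analysis requires; it adds
#' no information beyond interpolation. One-sided density: the integral of
#' `power` over `frequencies` approximates the series variance.
#'
#' @param x Numeric vector or matrix (one column per axis).
#' @param sample_rate Sampling rate (Hz).
#' @param segment_seconds Segment length (s); default 10.
#' @param overlap Fractional segment overlap; default 0.5.
#' @param zero_pad FFT length multiplier; default 4.
#' @return A `welch_spectrum`: `frequencies` (Hz) and `power` (matrix, one
#'   column per axis, density units x^2/Hz).
#' @export
welch_spectrum <- function(x, sample_rate, segment_seconds = 10,
                           overlap = 0.5, zero_pad = 4) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  seg_len <- round(segment_seconds * sample_rate)
  if (n < seg_len) {
    tremor_stop(sprintf("series shorter than one Welch segment (%d < %d)",
                        n, seg_len), "tremorcv_error_too_short")
  }
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  nfft <- seg_len * zero_pad
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  norm <- sample_rate * sum(w^2)
  n_keep <- floor(nfft / 2) + 1L
  freqs <- (seq_len(n_keep) - 1L) * sample_rate / nfft
  power <- matrix(0, n_keep, ncol(x))
  for (j in seq_len(ncol(x))) {
    acc <- numeric(n_keep)
    for (s in starts) {
      seg <- x[s:(s + seg_len - 1L), j]
      seg <- (seg - mean(seg)) * w
      sp <- stats::fft(c(seg, numeric(nfft - seg_len)))[seq_len(n_keep)]
      acc <- acc + Mod(sp)^2 / norm
    }
    p <- acc / length(starts)
    p[-1L] <- 2 * p[-1L]
    if (nfft %% 2 == 0) p[n_keep] <- p[n_keep] / 2
    power[, j] <- p
  }
  structure(list(frequencies = freqs, power = power,
                 sample_rate = sample_rate, n_segments = length(starts)),
            class = "welch_spectrum")
}

#' Detect the peak tremor frequency in a spectrum
#'
#' Per-axis densities are averaged into a combined spectrum; local maxima
#' inside the frequency-of-interest band are located, and those below
#' `threshold_fraction` of the combined spectrum's global maximum are
#' discarded. The highest-power qualifying peak is returned. Absence of a
#' qualifying peak is a value, not an error: recordings whose tremor is too
#' small to rise above the noise floor legitimately yield no peak.
#'
#' @param spectrum A `welch_spectrum`.
#' @param foi Frequency-of-interest band (Hz); default 3-8, within which hand
#'   tremor peaks are accepted.
#' @param threshold_fraction Minimum peak power as a fraction of the combined
#'   spectrum's global maximum; default 0.1.
#' @param axes Integer columns of the spectrum to combine; default all.
#' @return A `spectrum_peak`: the inputs plus `peak_frequency` and `peak_power`
#'   (`NA` when absent) and the combined spectrum.
#' @export
detect_peak_frequency <- function(spectrum, foi = c(3, 8),
                                  threshold_fraction = 0.1,
                                  axes = seq_len(ncol(spectrum$power))) {
  stopifnot(inherits(spectrum, "welch_spectrum"))
  combined <- rowMeans(spectrum$power[, axes, drop = FALSE])
  f <- spectrum$frequencies
  thr <- threshold_fraction * max(combined)
  in_foi <- which(f >= foi[1L] & f <= foi[2L])
  peak_frequency <- peak_power <- NA_real_
  if (length(in_foi) >= 1L) {
    n <- length(combined)
    is_max <- vapply(in_foi, function(i) {
      left_ok <- i == 1L || combined[i] > combined[i - 1L]
      right_ok <- i == n || combined[i] >= combined[i + 1L]
      left_ok && right_ok
    }, logical(1))
    cand <- in_foi[is_max & combined[in_foi] >= thr]
    if (length(cand)) {
      best <- cand[which.max(combined[cand])]
      peak_frequency <- f[best]
      peak_power <- combined[best]
    }
  }
  structure(list(frequencies = f, power = spectrum$power, combined = combined,
                 foi = foi, threshold_fraction = threshold_fraction,
                 axes = axes, peak_frequency = peak_frequency,
                 peak_power = peak_power,
                 bin_width = f[2L] - f[1L]),
            class = "spectrum_peak")
}

#' @export
print.spectrum_peak <- function(x, ...) {
  if (is.na(x$peak_frequency)) {
    cat("<spectrum_peak> no qualifying peak in the frequency-of-interest band\n")
  } else {
    cat(sprintf("<spectrum_peak> %.3f Hz (bin width %.4g Hz)\n",
                x$peak_frequency, x$bin_width))
  }
  invisible(x)
}

# interpolate over undetected frames so the spectrum sees a uniform series;
# dropout handling beyond this is the caller's QC concern
contiguous_axes <- function(trace, axes) {
  pos <- landmark_positions(trace, FINGERTIP_LANDMARK, axes = axes)
  pos[!trace$detected, ] <- NA_real_
  pos <- apply(pos, 2L, interp_na)
  if (!is.matrix(pos)) pos <- matrix(pos, ncol = length(axes))
  ok <- apply(is.finite(pos), 1L, all)
  first <- which(ok)[1L]
  last <- rev(which(ok))[1L]
  if (is.na(first) || last - first + 1L < 2L) {
    tremor_stop("fewer than 2 detected frames", "tremorcv_error_too_few_frames")
  }
  pos[first:last, , drop = FALSE]
}

#' Estimate the peak tremor frequency of a trajectory trace
#'
#' Band-passes the per-axis fingertip positions (2-10 Hz), computes Welch
#' spectra, and gates the peak to the frequency-of-interest band. For the
#' video-based method variants only the x and y axes enter the spectra (the
#' depth channel degrades frequency estimation); the optical motion-capture
#' variant uses all three.
#'
#' @param trace A `trajectory_trace` containing landmark 12.
#' @param variant One of [method_variants()].
#' @param band Position band-pass edges (Hz).
#' @inheritParams detect_peak_frequency
#' @inheritParams welch_spectrum
#' @return A `spectrum_peak` (`peak_frequency` is `NA` when no peak qualifies,
#'   including when too few frames are detected).
#' @export
estimate_peak_frequency <- function(trace, variant, band = c(2, 10),
                                    foi = c(3, 8), threshold_fraction = 0.1,
                                    segment_seconds = 10) {
  info <- variant_info(variant)
  pos <- tryCatch(contiguous_axes(trace, info$spectral_axes),
                  tremorcv_error_too_few_frames = function(e) NULL)
  empty <- structure(list(frequencies = numeric(0), power = NULL,
                          combined = numeric(0), foi = foi,
                          threshold_fraction = threshold_fraction,
                          axes = info$spectral_axes,
                          peak_frequency = NA_real_, peak_power = NA_real_,
                          bin_width = NA_real_),
                     class = "spectrum_peak")
  if (is.null(pos)) return(empty)
  filt <- tryCatch(bandpass(pos, trace$sample_rate, band[1L], band[2L]),
                   tremorcv_error_too_short = function(e) NULL)
  if (is.null(filt)) return(empty)
  spec <- tryCatch(
    welch_spectrum(filt, trace$sample_rate, segment_seconds = segment_seconds),
    tremorcv_error_too_short = function(e) NULL)
  if (is.null(spec)) return(empty)
  detect_peak_frequency(spec, foi = foi,
                        threshold_fraction = threshold_fraction)
}

#' Estimate the peak tremor frequency of an IMU recording
#'
#' Band-passes the tri-axial accelerations (the constant gravity component
#' falls below the low cutoff) and applies the same Welch + gating procedure
#' over all three axes.
#'
#' @param imu An `imu_series`.
#' @inheritParams estimate_peak_frequency
#' @return A `spectrum_peak`.
#' @export
imu_peak_frequency <- function(imu, band = c(2, 10), foi = c(3, 8),
                               threshold_fraction = 0.1,
                               segment_seconds = 10) {
  stopifnot(inherits(imu, "imu_series"))
  filt <- bandpass(imu$accel, imu$sample_rate, band[1L], band[2L])
  spec <- welch_spectrum(filt, imu$sample_rate,
                         segment_seconds = segment_seconds)
  detect_peak_frequency(spec, foi = foi, threshold_fraction = threshold_fraction)
}
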