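# Independent oracles used to cross-check the pipeline implementations.

# Brute-force turning-point scan: an interior index is a turning point iff it
# is the first minimum of its own window of radius w (the half-cycle of the
# fastest passband tremor). Computed per window via which.min, independently of
# the package's scan.
oracle_turning_points <- function(d, sample_rate, high = 10) {
  w <- ceiling(sample_rate / (2 * high))
  m <- length(d)
  out <- integer(0)
  for (i in seq_len(m)) {
    if (i == 1L || i == m) next
    lo <- max(1L, i - w)
    hi <- min(m, i + w)
    if (lo - 1L + which.min(d[lo:hi]) == i) out <- c(out, i)
  }
  out
}

# O(n^2) concordant/discordant pair count -> tau-b with tie correction
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  (conc - disc) / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}

# a displacement_series wrapper around an arbitrary filtered signal, for
# feeding detect_turning_points directly
make_displacement <- function(filtered, raw = abs(filtered) + 1,
                              sample_rate = 120, band = c(2, 10)) {
  structure(list(times = seq_along(filtered) / sample_rate,
                 raw = raw, filtered = filtered,
                 segment = rep(1L, length(filtered)),
                 sample_rate = sample_rate, variant = "OMC_XYZ",
                 units = "mm", band = band, n_interpolated = 0L),
            class = "displacement_series")
}

# single-landmark (id 12) world-mm trace from per-axis position matrices
make_trace_12 <- function(pos_matrix, sample_rate = 120, detected = NULL,
                          space = "world_mm") {
  n <- nrow(pos_matrix)
  pos <- array(0, dim = c(n, 1L, ncol(pos_matrix)))
  pos[, 1L, ] <- pos_matrix
  if (!is.null(detected)) pos[!detected, , ] <- NA_real_
  trajectory_trace((seq_len(n) - 1L) / sample_rate, pos, space,
                   landmark_ids = 12L, detected = detected,
                   sample_rate = sample_rate)
}
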