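# Readers/writers for landmark and IMU time series.
#
# Canonical on-disk format: a wide CSV (time_s, lm{NN}_{x,y,z}..., confidence,
# detected) plus a JSON sidecar `<path>.json` carrying space, sample_rate and
# frame resolution. Undetected frames have empty position cells, never zeros.

#' Write a trajectory trace to the canonical wide CSV
#'
#' @param trace A `trajectory_trace`.
#' @param path Output CSV path; a metadata sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trace, path) {
  stopifnot(inherits(trace, "trajectory_trace"))
  axes <- c("x", "y", "z")[seq_len(n_axes(trace))]
  cols <- list(time_s = trace$timestamps)
  for (j in seq_along(trace$landmark_ids)) {
    for (ax in seq_along(axes)) {
      cols[[sprintf("lm%d_%s", trace$landmark_ids[j], axes[ax])]] <-
        trace$positions[, j, ax]
    }
  }
  cols$confidence <- trace$confidence
  cols$detected <- as.integer(trace$detected)
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(format = "tremorcv_trajectory", schema_version = 1L,
               space = trace$space, sample_rate = trace$sample_rate,
               frame_resolution = trace$frame_resolution)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory trace
#'
#' Reads the canonical wide CSV (with its JSON sidecar when present), a plain
#' TSV export of 3D marker positions (`format_hint = "omc_tsv"`, columns
#' `time_s` then `lm{NN}_{x,y,z}`), or a self-contained JSON trace document
#' (`format_hint = "json"`, as written by [write_trajectory_json()]).
#' Malformed input is rejected with a named error: non-monotonic timestamps,
#' missing required columns, and landmarks with mixed axis counts each raise a
#' distinct condition class.
#'
#' @param path Input file path.
#' @param format_hint `"csv"` (default), `"omc_tsv"` or `"json"`.
#' @param space Coordinate space override when no sidecar is present.
#' @return A `trajectory_trace`. The sample rate is taken from the metadata, or
#'   inferred from the median timestamp spacing.
#' @export
read_trajectory <- function(path, format_hint = c("csv", "omc_tsv", "json"),
                            space = NULL) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) {
    tremor_stop(sprintf("file not found: %s", path), "tremorcv_error_io")
  }
  if (format_hint == "json") return(read_trajectory_json(path))
  sep <- if (format_hint == "omc_tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (!"time_s" %in% names(df)) {
    tremor_stop("required column `time_s` is missing",
                "tremorcv_error_missing_column")
  }
  tt <- df$time_s
  if (anyNA(tt) || any(diff(tt) <= 0)) {
    tremor_stop("timestamps must be strictly increasing",
                "tremorcv_error_timestamps")
  }

  lm_cols <- grep("^lm[0-9]+_[xyz]$", names(df), value = TRUE)
  if (length(lm_cols) == 0L) {
    tremor_stop("no landmark columns (lm{NN}_{x,y,z}) found",
                "tremorcv_error_missing_column")
  }
  ids <- as.integer(sub("^lm([0-9]+)_.*$", "\\1", lm_cols))
  ax <- sub("^lm[0-9]+_", "", lm_cols)
  uid <- sort(unique(ids))
  axes_per_lm <- vapply(uid, function(i) sum(ids == i), integer(1))
  if (length(unique(axes_per_lm)) != 1L) {
    tremor_stop("landmarks have mixed axis counts", "tremorcv_error_mixed_axes")
  }
  nax <- axes_per_lm[1L]
  axis_names <- c("x", "y", "z")[seq_len(nax)]
  pos <- array(NA_real_, dim = c(nrow(df), length(uid), nax))
  for (j in seq_along(uid)) {
    for (k in seq_len(nax)) {
      col <- sprintf("lm%d_%s", uid[j], axis_names[k])
      if (!col %in% names(df)) {
        tremor_stop(sprintf("required column `%s` is missing", col),
                    "tremorcv_error_missing_column")
      }
      pos[, j, k] <- df[[col]]
    }
  }

  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  space <- space %||% meta$space %||%
    if (format_hint == "omc_tsv") "world_mm" else "world_mm"
  detected <- if ("detected" %in% names(df)) as.logical(df$detected)
              else !apply(is.na(pos), 1L, all)
  confidence <- if ("confidence" %in% names(df)) df$confidence
                else as.numeric(detected)
  res <- meta$frame_resolution
  if (!is.null(res)) res <- as.numeric(unlist(res))
  trajectory_trace(tt, pos, space, landmark_ids = uid,
                   confidence = confidence, detected = detected,
                   sample_rate = meta$sample_rate %||% NULL,
                   frame_resolution = res)
}

#' Write a trajectory trace as a self-contained JSON document
#'
#' @param trace A `trajectory_trace`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(trace, path) {
  stopifnot(inherits(trace, "trajectory_trace"))
  doc <- list(format = "tremorcv_trajectory", schema_version = 1L,
              space = trace$space, sample_rate = trace$sample_rate,
              frame_resolution = trace$frame_resolution,
              landmark_ids = trace$landmark_ids,
              timestamps = trace$timestamps,
              confidence = trace$confidence, detected = trace$detected,
              # frames x landmarks x axes, flattened in axis-fastest order
              dim = dim(trace$positions),
              positions = as.vector(aperm(trace$positions, c(3, 2, 1))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

read_trajectory_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("timestamps", "positions", "dim", "space", "landmark_ids")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    tremor_stop(sprintf("required field `%s` is missing", miss[1L]),
                "tremorcv_error_missing_column")
  }
  d <- as.integer(doc$dim)
  pos <- aperm(array(as.numeric(doc$positions), dim = rev(d)), c(3, 2, 1))
  tt <- as.numeric(doc$timestamps)
  if (any(diff(tt) <= 0)) {
    tremor_stop("timestamps must be strictly increasing",
                "tremorcv_error_timestamps")
  }
  trajectory_trace(tt, pos, doc$space,
                   landmark_ids = as.integer(doc$landmark_ids),
                   confidence = doc$confidence, detected = doc$detected,
                   sample_rate = doc$sample_rate,
                   frame_resolution = doc$frame_resolution)
}

#' Write an IMU acceleration series
#'
#' @param imu An `imu_series` (see [synthesize_imu()]).
#' @param path Output CSV path (columns time_s, ax, ay, az).
#' @return `path`, invisibly.
#' @export
write_imu <- function(imu, path) {
  stopifnot(inherits(imu, "imu_series"))
  df <- data.frame(time_s = imu$timestamps, ax = imu$accel[, 1L],
                   ay = imu$accel[, 2L], az = imu$accel[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an IMU acceleration series
#'
#' @param path CSV with columns time_s, ax, ay, az (m/s^2).
#' @return An `imu_series`.
#' @export
read_imu <- function(path) {
  if (!file.exists(path)) {
    tremor_stop(sprintf("file not found: %s", path), "tremorcv_error_io")
  }
  df <- utils::read.csv(path)
  need <- c("time_s", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    tremor_stop(sprintf("required column `%s` is missing", miss[1L]),
                "tremorcv_error_missing_column")
  }
  if (any(diff(df$time_s) <= 0)) {
    tremor_stop("timestamps must be strictly increasing",
                "tremorcv_error_timestamps")
  }
  structure(list(timestamps = df$time_s,
                 accel = as.matrix(df[, c("ax", "ay", "az")]),
                 sample_rate = 1 / stats::median(diff(df$time_s))),
            class = "imu_series")
}

#' Extract hand landmarks from a video (optional adapter)
#'
#' Thin adapter seam for an external hand-tracking backend. The package never
#' depends on such a backend: with the default character backend name this
#' function raises a named `tremorcv_error_backend_unavailable` condition. For
#' testing or integration, `backend` may be an R function `function(path)`
#' returning a `trajectory_trace`.
#'
#' @param path Video file path.
#' @param backend Backend name (unavailable here) or an R callback.
#' @return A `trajectory_trace` in normalized space.
#' @export
extract_landmarks_from_video <- function(path, backend = "mediapipe") {
  if (is.function(backend)) {
    if (!file.exists(path)) {
      tremor_stop(sprintf("unreadable video: %s", path), "tremorcv_error_io")
    }
    out <- backend(path)
    if (!inherits(out, "trajectory_trace")) {
      tremor_stop("backend must return a trajectory_trace",
                  "tremorcv_error_backend")
    }
    if (!any(out$detected)) {
      tremor_stop("no hand detected in any frame", "tremorcv_error_no_hand")
    }
    return(out)
  }
  tremor_stop(sprintf("hand-tracking backend '%s' is not available", backend),
              "tremorcv_error_backend_unavailable")
}
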