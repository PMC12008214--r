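# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulator determinism never leaks into
#' (or depends on) the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# classed error so callers/tests can dispatch on failure kind
tremor_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "tremorcv_error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    tremor_stop(sprintf("`%s` must be a single finite number", name),
                "tremorcv_error_config")
  }
  bad_low <- if (strict_lower) x <= lower else x < lower
  bad_high <- if (strict_upper) x >= upper else x > upper
  if (bad_low || bad_high) {
    tremor_stop(sprintf("`%s` = %g is outside its valid range", name, x),
                "tremorcv_error_config")
  }
  invisible(x)
}

assert_unit_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x))) {
    tremor_stop(sprintf("`%s` must be a finite 3-vector", name),
                "tremorcv_error_config")
  }
  n <- sqrt(sum(x^2))
  if (abs(n - 1) > 1e-6) {
    tremor_stop(sprintf("`%s` must have unit norm (got %g)", name, n),
                "tremorcv_error_config")
  }
  invisible(x)
}

unitize <- function(x) x / sqrt(sum(x^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Orthonormal hand-local frame from a palm normal
#'
#' Columns are the local x (finger direction), y (across the palm) and
#' z (palm normal) axes expressed in world coordinates. The in-plane axes are
#' completed deterministically from the world x axis (world y when degenerate).
#' @noRd
hand_basis <- function(palm_normal) {
  n <- unitize(palm_normal)
  seed_axis <- c(1, 0, 0)
  if (abs(sum(seed_axis * n)) > 0.99) seed_axis <- c(0, 1, 0)
  ex <- unitize(seed_axis - sum(seed_axis * n) * n)
  ey <- cross3(n, ex)
  cbind(ex, ey, n, deparse.level = 0)
}

# linear interpolation over interior NA runs; leading/trailing NAs left as-is
interp_na <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) < 2L) return(x)
  out <- x
  inner <- seq(idx[1L], idx[length(idx)])
  out[inner] <- stats::approx(idx, x[idx], xout = inner)$y
  out
}
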