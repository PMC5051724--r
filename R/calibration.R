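#' Detect stationary windows in a recording
#'
#' Splits the recording into consecutive non-overlapping windows of
#' `window_s` seconds and keeps those where the standard deviation of
#' every axis falls below `sd_threshold_mg`. These near-rest windows are
#' the anchor points for gravity-sphere auto-calibration: at rest the
#' vector magnitude should equal 1 g = 1000 mg.
#'
#' @param rec An [raw_recording()].
#' @param window_s Window length in seconds (default 10).
#' @param sd_threshold_mg Per-axis SD threshold in mg (default 13).
#' @return Tibble with one row per stationary window: half-open sample
#'   index range `start_index`, `end_index` plus the per-axis window
#'   means `mx`, `my`, `mz` (mg).
#' @export
detect_stationary_windows <- function(rec, window_s = 10, sd_threshold_mg = 13) {
  fs <- rec_fs(rec)
  n <- as.integer(round(fs * window_s))
  if (n < 2L) {
    abort("`window_s` x fs must cover at least 2 samples.",
          class = "accelcut_config_error")
  }
  nw <- nrow(rec) %/% n
  empty <- tibble::tibble(start_index = integer(), end_index = integer(),
                          mx = numeric(), my = numeric(), mz = numeric())
  if (nw == 0L) return(empty)
  idx <- seq_len(nw * n)
  # column-per-window reshape; colMeans/col SDs without per-window loops
  win_stats <- function(v) {
    m <- matrix(v[idx], nrow = n)
    mu <- colMeans(m)
    s2 <- colSums((m - rep(mu, each = n))^2) / (n - 1)
    list(mean = mu, sd = sqrt(s2))
  }
  sx <- win_stats(rec$x); sy <- win_stats(rec$y); sz <- win_stats(rec$z)
  keep <- sx$sd < sd_threshold_mg & sy$sd < sd_threshold_mg & sz$sd < sd_threshold_mg
  if (!any(keep)) return(empty)
  w <- which(keep)
  tibble::tibble(
    start_index = (w - 1L) * n + 1L,
    end_index = w * n + 1L,
    mx = sx$mean[w], my = sy$mean[w], mz = sz$mean[w]
  )
}

#' Estimate offset/gain calibration from stationary window means
#'
#' Fits per-axis gain and offset so that calibrated stationary means lie
#' on the 1000-mg gravity sphere, by iteratively re-weighted least
#' squares against the closest point on the sphere. With fewer than
#' `min_windows` windows, or when all window means point within 30
#' degrees of a single direction (no orientation diversity, so the
#' sphere is unidentifiable), the identity calibration is returned with
#' `flagged = TRUE`.
#'
#' @param window_means Data frame/tibble with columns `mx`, `my`, `mz`
#'   (mg), one row per stationary window — the output of
#'   [detect_stationary_windows()] — or a 3-column numeric matrix.
#' @param min_windows Minimum number of windows for a fit (default 10).
#' @param max_iter,tol Iteration cap and parameter-change convergence
#'   tolerance of the sphere fit.
#' @return An object of class `accel_calibration`: list with `offset`
#'   (mg, length 3), `gain` (length 3), `residual_mg` (mean absolute
#'   deviation of calibrated stationary magnitudes from 1000 mg),
#'   `n_windows`, `flagged`, `converged`, `n_iter`.
#' @export
estimate_calibration <- function(window_means, min_windows = 10,
                                 max_iter = 100, tol = 1e-9) {
  m <- as_window_matrix(window_means)
  if (nrow(m) == 0L) {
    abort("`window_means` is empty; cannot estimate a calibration.",
          class = "accelcut_precondition_error")
  }
  identity_cal <- function(flag) {
    new_calibration(offset = c(0, 0, 0), gain = c(1, 1, 1),
                    residual_mg = mean(abs(row_norms(m) - 1000)),
                    n_windows = nrow(m), flagged = flag,
                    converged = FALSE, n_iter = 0L)
  }
  if (nrow(m) < min_windows || !orientation_diverse(m)) {
    return(identity_cal(TRUE))
  }
  # Gauss-Newton on theta = (gain, offset): residual per window is the
  # distance of the calibrated mean to its closest point on the sphere,
  # e_w = |gain o m_w + offset| - 1000. Levenberg damping guards the
  # rare ill-conditioned step when orientations barely span an axis.
  theta <- c(1, 1, 1, 0, 0, 0)
  converged <- FALSE
  it <- 0L
  lambda <- 0
  for (it in seq_len(max_iter)) {
    cal <- sweep(sweep(m, 2L, theta[1:3], `*`), 2L, theta[4:6], `+`)
    r <- row_norms(cal)
    e <- r - 1000
    J <- cbind(cal * m / r, cal / r)
    H <- crossprod(J)
    step <- tryCatch(
      solve(H + diag(lambda + 1e-12, 6), -crossprod(J, e)),
      error = function(err) NULL)
    if (is.null(step)) {
      lambda <- max(lambda * 10, 1e-6)
      next
    }
    theta_new <- theta + as.vector(step)
    cal_new <- sweep(sweep(m, 2L, theta_new[1:3], `*`), 2L, theta_new[4:6], `+`)
    if (sum((row_norms(cal_new) - 1000)^2) > sum(e^2) && lambda < 1e6) {
      lambda <- max(lambda * 10, 1e-6)
      next
    }
    lambda <- lambda / 10
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  gain <- theta[1:3]
  offset <- theta[4:6]
  if (any(gain <= 0.5 | gain >= 2) || any(abs(offset) >= 500)) {
    # implausible sensor model: keep the data untouched instead
    return(identity_cal(TRUE))
  }
  cal <- sweep(sweep(m, 2L, gain, `*`), 2L, offset, `+`)
  residual <- mean(abs(row_norms(cal) - 1000))
  if (residual > mean(abs(row_norms(m) - 1000))) {
    # a fit must not be worse than leaving the data alone
    return(identity_cal(TRUE))
  }
  new_calibration(offset = offset, gain = gain, residual_mg = residual,
                  n_windows = nrow(m), flagged = FALSE,
                  converged = converged, n_iter = it)
}

as_window_matrix <- function(window_means) {
  if (is.matrix(window_means)) {
    stopifnot(ncol(window_means) == 3L)
    m <- window_means
  } else {
    cols <- if (all(c("mx", "my", "mz") %in% names(window_means))) {
      c("mx", "my", "mz")
    } else if (all(c("x", "y", "z") %in% names(window_means))) {
      c("x", "y", "z")
    } else {
      abort("`window_means` needs columns mx,my,mz (or x,y,z).",
            class = "accelcut_config_error")
    }
    m <- as.matrix(window_means[cols])
  }
  storage.mode(m) <- "double"
  m
}

row_norms <- function(m) sqrt(rowSums(m^2))

# Orientation diversity: if every window mean lies within 30 degrees of
# the common mean direction the sphere fit is degenerate (offset and
# gain trade off along one axis).
orientation_diverse <- function(m, cone_deg = 30) {
  u <- m / row_norms(m)
  centre <- colMeans(u)
  nc <- sqrt(sum(centre^2))
  if (nc < 1e-12) return(TRUE)
  centre <- centre / nc
  ang <- acos(pmin(1, pmax(-1, as.vector(u %*% centre)))) * 180 / pi
  max(ang) > cone_deg
}

new_calibration <- function(offset, gain, residual_mg, n_windows,
                            flagged, converged, n_iter) {
  structure(list(offset = as.numeric(offset), gain = as.numeric(gain),
                 residual_mg = residual_mg, n_windows = as.integer(n_windows),
                 flagged = flagged, converged = converged,
                 n_iter = as.integer(n_iter)),
            class = "accel_calibration")
}

#' @export
print.accel_calibration <- function(x, ...) {
  cat("<accel_calibration>\n")
  cat(sprintf("  gain:     %s\n", paste(sprintf("%.5f", x$gain), collapse = ", ")))
  cat(sprintf("  offset:   %s mg\n", paste(sprintf("%.2f", x$offset), collapse = ", ")))
  cat(sprintf("  residual: %.3f mg over %d stationary windows%s\n",
              x$residual_mg, x$n_windows,
              if (x$flagged) "  [flagged: identity fallback]" else ""))
  invisible(x)
}

#' @export
tidy.accel_calibration <- function(x, ...) {
  tibble::tibble(axis = c("x", "y", "z"), gain = x$gain, offset_mg = x$offset)
}

#' @export
glance.accel_calibration <- function(x, ...) {
  tibble::tibble(residual_mg = x$residual_mg, n_windows = x$n_windows,
                 flagged = x$flagged, converged = x$converged, n_iter = x$n_iter)
}

#' Apply a calibration to a recording
#'
#' Replaces every axis value by `gain * value + offset`. Metadata is
#' preserved; the transform is affine and exactly invertible.
#'
#' @param rec An [raw_recording()].
#' @param cal An `accel_calibration` from [estimate_calibration()].
#' @return The calibrated recording.
#' @export
apply_calibration <- function(rec, cal) {
  stopifnot(inherits(cal, "accel_calibration"))
  out <- rec
  out$x <- cal$gain[1] * rec$x + cal$offset[1]
  out$y <- cal$gain[2] * rec$y + cal$offset[2]
  out$z <- cal$gain[3] * rec$z + cal$offset[3]
  out
}

#' Auto-calibrate a recording end to end
#'
#' Convenience wrapper: [detect_stationary_windows()] then
#' [estimate_calibration()] then [apply_calibration()].
#'
#' @inheritParams detect_stationary_windows
#' @inheritParams estimate_calibration
#' @return List with `recording` (calibrated) and `calibration`.
#' @export
calibrate_recording <- function(rec, window_s = 10, sd_threshold_mg = 13,
                                min_windows = 10) {
  win <- detect_stationary_windows(rec, window_s, sd_threshold_mg)
  cal <- if (nrow(win) == 0L) {
    new_calibration(c(0, 0, 0), c(1, 1, 1), residual_mg = NA_real_,
                    n_windows = 0L, flagged = TRUE, converged = FALSE, n_iter = 0L)
  } else {
    estimate_calibration(win, min_windows = min_windows)
  }
  list(recording = apply_calibration(rec, cal), calibration = cal)
}
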