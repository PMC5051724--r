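#' Split a recording into fixed-length epochs
#'
#' Epochs are consecutive, non-overlapping and anchored at the recording
#' start; a trailing partial epoch is dropped (padding would bias MAD).
#' At the protocol's 100 Hz and 5-s epochs each epoch holds n = 500
#' samples.
#'
#' @param rec An [raw_recording()].
#' @param epoch_s Epoch length in seconds (default 5).
#' @return Tibble with one row per epoch: `epoch`, `start_t`, `n`,
#'   `mean_magnitude` (mg) and a list-column `magnitudes` of per-sample
#'   vector magnitudes r_i = sqrt(x^2 + y^2 + z^2) in mg.
#' @export
epoch_signal <- function(rec, epoch_s = 5) {
  em <- epoch_magnitude_matrix(rec, epoch_s)
  if (is.null(em)) {
    return(tibble::tibble(epoch = integer(), start_t = numeric(), n = integer(),
                          mean_magnitude = numeric(), magnitudes = list()))
  }
  tibble::tibble(
    epoch = seq_len(ncol(em$mat)),
    start_t = em$start_t,
    n = em$n,
    mean_magnitude = colMeans(em$mat),
    magnitudes = lapply(seq_len(ncol(em$mat)), function(j) em$mat[, j])
  )
}

# Internal fast path: per-sample magnitudes reshaped to an n x n_epochs
# matrix (one column per full epoch); trailing partial epoch dropped.
epoch_magnitude_matrix <- function(rec, epoch_s = 5) {
  fs <- rec_fs(rec)
  n <- as.integer(round(fs * epoch_s))
  if (n < 1L) {
    abort("`epoch_s` x fs must be at least 1 sample.", class = "accelcut_config_error")
  }
  ne <- nrow(rec) %/% n
  if (ne == 0L) return(NULL)
  idx <- seq_len(ne * n)
  r <- sqrt(rec$x[idx]^2 + rec$y[idx]^2 + rec$z[idx]^2)
  list(mat = matrix(r, nrow = n), n = n,
       start_t = rec$t[(seq_len(ne) - 1L) * n + 1L])
}

#' Mean Amplitude Deviation of one epoch
#'
#' MAD = (1/n) * sum_i |r_i - rbar|, the mean absolute deviation of the
#' per-sample vector magnitudes about their epoch mean, in mg. The static
#' (gravity) component cancels in the subtraction, so MAD needs no
#' filtering and no calibration to first order.
#'
#' @param magnitudes Numeric vector of per-sample vector magnitudes (mg).
#' @return MAD in mg (non-negative scalar).
#' @export
compute_mad <- function(magnitudes) {
  if (length(magnitudes) < 1L) {
    abort("An epoch needs at least one sample.", class = "accelcut_precondition_error")
  }
  mean(abs(magnitudes - mean(magnitudes)))
}

#' Euclidean Norm Minus One of one epoch
#'
#' Per-sample e_i = r_i - 1000 mg subtracts one gravitational unit from
#' the vector magnitude; negative values are rounded up to zero. With
#' `truncate_per_sample = TRUE` (the default, matching the common raw
#' toolchain) each e_i is clamped before averaging over the epoch; with
#' `FALSE` the epoch mean of raw e_i is computed first and then clamped.
#'
#' @inheritParams compute_mad
#' @param truncate_per_sample Clamp negatives per sample (default) or
#'   only on the epoch mean.
#' @return ENMO in mg (non-negative scalar).
#' @export
compute_enmo <- function(magnitudes, truncate_per_sample = TRUE) {
  if (length(magnitudes) < 1L) {
    abort("An epoch needs at least one sample.", class = "accelcut_precondition_error")
  }
  e <- magnitudes - 1000
  if (truncate_per_sample) mean(pmax(e, 0)) else max(mean(e), 0)
}

#' Compute per-epoch ENMO and MAD for a recording
#'
#' @param rec An [raw_recording()] (already calibrated if desired; see
#'   [calibrate_recording()]).
#' @param epoch_s Epoch length in seconds (default 5).
#' @param enmo_truncation `"per_sample"` (default) or `"epoch"`; see
#'   [compute_enmo()].
#' @return Tibble with one row per full epoch: `epoch_start`,
#'   `participant_id`, `brand`, `placement`, `activity_id` (`NA` until
#'   [trim_and_label()]), `enmo_mg`, `mad_mg`.
#' @export
compute_epoch_metrics <- function(rec, epoch_s = 5,
                                  enmo_truncation = c("per_sample", "epoch")) {
  enmo_truncation <- match.arg(enmo_truncation)
  em <- epoch_magnitude_matrix(rec, epoch_s)
  if (is.null(em)) {
    return(tibble::tibble(epoch_start = numeric(), participant_id = character(),
                          brand = character(), placement = character(),
                          activity_id = integer(), enmo_mg = numeric(),
                          mad_mg = numeric()))
  }
  mat <- em$mat
  n <- em$n
  mu <- colMeans(mat)
  mad <- colMeans(abs(mat - rep(mu, each = n)))
  enmo <- if (enmo_truncation == "per_sample") {
    colMeans(pmax(mat - 1000, 0))
  } else {
    pmax(mu - 1000, 0)
  }
  tibble::tibble(
    epoch_start = em$start_t,
    participant_id = rec_participant(rec),
    brand = rec_brand(rec),
    placement = rec_placement(rec),
    activity_id = NA_integer_,
    enmo_mg = enmo,
    mad_mg = mad
  )
}
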