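#' Build a raw tri-axial recording
#'
#' A raw recording is a tibble with one row per sample and columns `t`
#' (seconds since recording start), `x`, `y`, `z` (acceleration in
#' milligravity, mg). Sampling frequency and device metadata travel as
#' attributes so the object stays a plain data frame for dplyr work while
#' downstream stages can recover `fs`, brand and wear site.
#'
#' @param samples Data frame with numeric columns `t`, `x`, `y`, `z`.
#'   Axes must already be in mg (use `units = "g"` in [read_raw_csv()] to
#'   convert on read).
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param brand Device brand, one of `"AG"`, `"GA"`, `"OTHER"`.
#' @param placement Wear site, one of `"hip"`, `"wrist"`, `"other"`.
#' @param participant_id Opaque participant identifier.
#' @param validate Check the time base (strictly increasing, uniform step
#'   `1/fs` within 1e-6 s) and axis finiteness. Disable only for signals
#'   you have just generated on an exact grid.
#' @return A tibble of class `accel_raw` with attributes `fs`, `brand`,
#'   `placement`, `participant_id`.
#' @seealso [read_raw_csv()], [epoch_signal()]
#' @export
raw_recording <- function(samples, fs,
                          brand = c("OTHER", "AG", "GA"),
                          placement = c("other", "hip", "wrist"),
                          participant_id = NA_character_,
                          validate = TRUE) {
  brand <- match.arg(toupper(brand[1]), c("OTHER", "AG", "GA"))
  placement <- match.arg(tolower(placement[1]), c("other", "hip", "wrist"))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).", class = "accelcut_config_error")
  }
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(samples))) {
    abort(paste0("`samples` must have columns ", paste(need, collapse = ", "), "."),
          class = "accelcut_config_error")
  }
  rec <- tibble::as_tibble(samples[need])
  if (nrow(rec) < 1L) {
    abort("A recording needs at least one sample.", class = "accelcut_validation_error")
  }
  if (validate) {
    validate_time_base(rec$t, fs)
    bad <- !is.finite(rec$x) | !is.finite(rec$y) | !is.finite(rec$z)
    if (any(bad)) {
      abort(sprintf("Non-finite acceleration at sample %d.", which(bad)[1]),
            class = "accelcut_validation_error")
    }
  }
  structure(rec,
            class = c("accel_raw", class(tibble::tibble())),
            fs = fs, brand = brand, placement = placement,
            participant_id = as.character(participant_id))
}

validate_time_base <- function(t, fs, tol = 1e-6) {
  if (length(t) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      i <- which(dt <= 0)[1]
      abort(sprintf("Timestamps must be strictly increasing; violation at row %d.", i + 1L),
            class = "accelcut_validation_error")
    }
    if (any(abs(dt - 1 / fs) > tol)) {
      i <- which(abs(dt - 1 / fs) > tol)[1]
      abort(sprintf(
        "Non-uniform sampling at row %d: step %.8f s, expected %.8f s (tol 1e-6).",
        i + 1L, dt[i], 1 / fs), class = "accelcut_validation_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.accel_raw <- function(x, ...) {
  cat(sprintf("<accel_raw> %d samples @ %g Hz (%.1f s), brand=%s, placement=%s, participant=%s\n",
              nrow(x), rec_fs(x), nrow(x) / rec_fs(x), rec_brand(x),
              rec_placement(x), rec_participant(x)))
  NextMethod()
}

#' Recording metadata accessors
#'
#' @param rec An `accel_raw` recording.
#' @return A scalar: sampling frequency (Hz), brand, placement or
#'   participant id.
#' @export
rec_fs <- function(rec) attr(rec, "fs")

#' @rdname rec_fs
#' @export
rec_brand <- function(rec) attr(rec, "brand") %||% "OTHER"

#' @rdname rec_fs
#' @export
rec_placement <- function(rec) attr(rec, "placement") %||% "other"

#' @rdname rec_fs
#' @export
rec_participant <- function(rec) attr(rec, "participant_id") %||% NA_character_
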