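#' Read a raw acceleration CSV
#'
#' Two plain-text dialects are supported. Dialect `"timestamped"` has a
#' header `t,x,y,z` with `t` in seconds since recording start. Dialect
#' `"headerless_with_meta"` carries comment lines `# fs_hz=<Hz>` and
#' optionally `# start=<ISO-8601>` followed by `x,y,z` rows (with or
#' without an `x,y,z` header line); timestamps are regenerated from
#' `fs_hz`. Proprietary binary device formats are out of scope: export to
#' CSV first.
#'
#' @param path Path to the CSV file.
#' @param dialect `"timestamped"` or `"headerless_with_meta"`.
#' @param units Units of the stored axes; `"g"` values are multiplied by
#'   1000 so that all downstream computation is in mg.
#' @param fs Sampling frequency in Hz. Required for the timestamped
#'   dialect only if it cannot be inferred from the timestamps; ignored
#'   (header wins) for the headerless dialect.
#' @inheritParams raw_recording
#' @return An [raw_recording()] tibble in mg.
#' @export
read_raw_csv <- function(path, dialect = c("timestamped", "headerless_with_meta"),
                         units = c("mg", "g"), fs = NULL,
                         brand = "OTHER", placement = "other",
                         participant_id = NA_character_) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "accelcut_io_error")
  }
  if (dialect == "timestamped") {
    dat <- read_numeric_csv(path, c("t", "x", "y", "z"), skip_comments = TRUE)
    if (is.null(fs)) {
      if (nrow(dat) < 2L) {
        abort("Cannot infer `fs` from a single-row timestamped file; pass `fs`.",
              class = "accelcut_config_error")
      }
      fs <- 1 / stats::median(diff(dat$t))
    }
  } else {
    meta <- parse_meta_header(path)
    if (is.na(meta$fs_hz)) {
      abort("headerless_with_meta dialect requires a `# fs_hz=<Hz>` header line.",
            class = "accelcut_config_error")
    }
    fs <- meta$fs_hz
    dat <- read_numeric_csv(path, c("x", "y", "z"), skip_comments = TRUE)
    dat$t <- (seq_len(nrow(dat)) - 1) / fs
  }
  if (units == "g") {
    dat$x <- dat$x * 1000
    dat$y <- dat$y * 1000
    dat$z <- dat$z * 1000
  }
  raw_recording(dat, fs = fs, brand = brand, placement = placement,
                participant_id = participant_id)
}

# Strict numeric CSV reader: any cell that fails to parse is reported with
# its 1-based line number in the file (header and comment lines included).
read_numeric_csv <- function(path, cols, skip_comments = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    abort(sprintf("No data rows in %s.", path), class = "accelcut_parse_error")
  }
  first <- tolower(gsub("\\s", "", lines[1]))
  has_header <- identical(first, paste(cols, collapse = ","))
  if (has_header) {
    line_no <- line_no[-1]
    lines <- lines[-1]
  }
  if (length(lines) == 0L) {
    abort(sprintf("No data rows in %s.", path), class = "accelcut_parse_error")
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(cols))) {
    i <- which(nf != length(cols))[1]
    abort(sprintf("Malformed row at line %d of %s: expected %d fields, found %d.",
                  line_no[i], path, length(cols), nf[i]),
          class = "accelcut_parse_error")
  }
  mat <- suppressWarnings(matrix(as.numeric(unlist(parts)),
                                 ncol = length(cols), byrow = TRUE))
  if (anyNA(mat)) {
    i <- which(apply(is.na(mat), 1L, any))[1]
    abort(sprintf("Malformed row at line %d of %s: non-numeric field.",
                  line_no[i], path), class = "accelcut_parse_error")
  }
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- cols
  out
}

parse_meta_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- trimws(lines[startsWith(trimws(lines), "#")])
  get <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), meta_lines, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, "\\s*="), "", hit[1]))
  }
  list(fs_hz = suppressWarnings(as.numeric(get("fs_hz"))), start = get("start"))
}

#' Read an activity log sheet
#'
#' The log is a CSV with columns `activity_id`, `label`, `start`, `end`.
#' Times are either plain seconds since recording start or ISO-8601
#' date-times; in the latter case supply `origin` (the recording start
#' time) so they can be converted to seconds. Activity ids follow the
#' laboratory protocol: 1-11 are sedentary postures (lying/sitting),
#' 12-16 the upright activities (standing still, washing pots, dusting,
#' sweeping floor, self-paced walk).
#'
#' @param path Path to the log CSV.
#' @param origin Recording start time (POSIXct or ISO-8601 string); only
#'   needed when `start`/`end` are date-times.
#' @return A tibble `activity_id, label, start, end` (seconds), validated
#'   to be time-ordered and non-overlapping with `start < end`.
#' @export
read_activity_log <- function(path, origin = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "accelcut_io_error")
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(dat) == 0L) {
    return(tibble::tibble(activity_id = integer(), label = character(),
                          start = numeric(), end = numeric()))
  }
  need <- c("activity_id", "label", "start", "end")
  if (!all(need %in% names(dat))) {
    abort("Activity log must have columns activity_id, label, start, end.",
          class = "accelcut_parse_error")
  }
  out <- tibble::tibble(
    activity_id = as.integer(dat$activity_id),
    label = dat$label,
    start = parse_log_time(dat$start, origin),
    end = parse_log_time(dat$end, origin)
  )
  validate_activity_log(out)
}

parse_log_time <- function(x, origin) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  tt <- as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(tt)) {
    abort("Unparseable time in activity log (neither seconds nor ISO-8601).",
          class = "accelcut_parse_error")
  }
  if (is.null(origin)) {
    abort("Date-time log entries need `origin` (the recording start time).",
          class = "accelcut_config_error")
  }
  if (is.character(origin)) origin <- as.POSIXct(origin, tz = "UTC",
                                                 tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  as.numeric(difftime(tt, origin, units = "secs"))
}

validate_activity_log <- function(log) {
  if (nrow(log) == 0L) return(log)
  if (anyNA(log$activity_id) || any(log$activity_id < 1L | log$activity_id > 16L)) {
    abort("activity_id must be an integer in 1..16.", class = "accelcut_validation_error")
  }
  if (any(log$start >= log$end)) {
    i <- which(log$start >= log$end)[1]
    abort(sprintf("Activity %d has start >= end.", log$activity_id[i]),
          class = "accelcut_validation_error")
  }
  ord <- order(log$start)
  log <- log[ord, ]
  if (nrow(log) > 1L && any(log$start[-1] < log$end[-nrow(log)])) {
    abort("Activity log entries overlap.", class = "accelcut_validation_error")
  }
  log
}

#' Write / read an epoch-metric table
#'
#' Epoch tables carry one row per 5-s (by default) epoch with both
#' intensity metrics and provenance. Values are written with full
#' (shortest round-trip) decimal precision, so a write/read cycle is
#' value-exact to within one unit in the last place of a double.
#'
#' @param metrics Tibble as produced by [compute_epoch_metrics()] or
#'   [trim_and_label()], with columns `epoch_start`, `participant_id`,
#'   `brand`, `placement`, `activity_id`, `enmo_mg`, `mad_mg`.
#' @param path Output/input CSV path.
#' @return `write_epoch_table()` returns `path` invisibly;
#'   `read_epoch_table()` returns the tibble.
#' @export
write_epoch_table <- function(metrics, path) {
  if (is.null(metrics) || nrow(metrics) == 0L) {
    abort("Refusing to write an empty epoch table.", class = "accelcut_precondition_error")
  }
  cols <- c("epoch_start", "participant_id", "brand", "placement",
            "activity_id", "enmo_mg", "mad_mg")
  missing <- setdiff(cols, names(metrics))
  if (length(missing)) {
    abort(paste0("Epoch table is missing columns: ", paste(missing, collapse = ", ")),
          class = "accelcut_validation_error")
  }
  readr::write_csv(metrics[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_epoch_table
#' @export
read_epoch_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "accelcut_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    epoch_start = readr::col_double(),
                    participant_id = readr::col_character(),
                    brand = readr::col_character(),
                    placement = readr::col_character(),
                    activity_id = readr::col_integer(),
                    enmo_mg = readr::col_double(),
                    mad_mg = readr::col_double()
                  ))
}
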