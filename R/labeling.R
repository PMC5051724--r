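#' Protocol activities and discriminations
#'
#' The laboratory protocol has 16 activities: ids 1-4 lying postures,
#' 5-11 sitting postures (together the pooled "sedentary behaviours"
#' class) and 12-16 the upright light-intensity activities. Each of the
#' five discriminations contrasts the pooled sedentary class against one
#' upright activity.
#'
#' @return `protocol_activities()`: tibble `activity_id`, `label`,
#'   `posture`; `discrimination_ids()`: named integer vector mapping
#'   discrimination name to target activity id.
#' @export
protocol_activities <- function() {
  tibble::tibble(
    activity_id = 1:16,
    label = c(
      "lying flat on back", "lying on back, legs bent",
      "lying on side, legs straight", "lying on side, legs bent",
      "sitting, feet on floor", "sitting, legs crossed",
      "sitting, foot on thigh", "sitting, legs stretched",
      "sitting, legs bent under chair", "sitting, typing",
      "sitting, mobile phone games", "standing still",
      "washing pots", "dusting", "sweeping floor", "self-paced walk"
    ),
    posture = c(rep("lying", 4), rep("sitting", 7), rep("upright", 5))
  )
}

#' @rdname protocol_activities
#' @export
discrimination_ids <- function() {
  c(standing = 12L, washing_pots = 13L, dusting = 14L,
    sweeping = 15L, walk = 16L)
}

sedentary_ids <- function() 1:11

#' Trim activity transitions and label epochs
#'
#' Joins an epoch-metric table to the activity log. The first and last
#' `trim_s` seconds of every activity window are excluded (transitional
#' movement), so with the default 30 s only the central 4 minutes of a
#' 5-minute activity are kept. An epoch is labeled only if it lies wholly
#' inside the trimmed window; epochs straddling a boundary or falling in
#' breaks are dropped.
#'
#' @param metrics Epoch tibble from [compute_epoch_metrics()].
#' @param log Activity log tibble from [read_activity_log()] (times in
#'   seconds on the same clock as `epoch_start`).
#' @param trim_s Seconds trimmed from each end of every activity
#'   (default 30).
#' @param epoch_s Epoch length in seconds used to compute the epoch end
#'   (default 5).
#' @return The labeled epoch tibble (same columns, `activity_id` filled),
#'   restricted to labeled epochs.
#' @export
trim_and_label <- function(metrics, log, trim_s = 30, epoch_s = 5) {
  if (nrow(log) == 0L) {
    abort("Activity log is empty; nothing to label.", class = "accelcut_precondition_error")
  }
  short <- log$end - log$start <= 2 * trim_s
  if (any(short)) {
    abort(sprintf("Activity %d (%.0f s) is not longer than 2 x trim_s = %.0f s.",
                  log$activity_id[which(short)[1]],
                  (log$end - log$start)[which(short)[1]], 2 * trim_s),
          class = "accelcut_validation_error")
  }
  lo <- log$start + trim_s
  hi <- log$end - trim_s
  s <- metrics$epoch_start
  e <- s + epoch_s
  # windows are non-overlapping, so each epoch matches at most one
  win <- findInterval(s, lo)
  inside <- win >= 1L & s >= lo[pmax(win, 1L)] & e <= hi[pmax(win, 1L)]
  out <- metrics[inside, , drop = FALSE]
  out$activity_id <- log$activity_id[win[inside]]
  out
}

#' Assemble one discrimination dataset
#'
#' Builds the labeled observations for one binary discrimination:
#' pooled sedentary behaviours (activities 1-11, label 0) versus a
#' single upright activity (label 1). At the default
#' `"participant_activity_mean"` granularity each participant contributes
#' one observation per activity — the mean metric over that activity's
#' labeled epochs — i.e. 11 sedentary observations and 1 positive
#' observation per participant. At `"epoch"` granularity every labeled
#' epoch is an observation.
#'
#' @param set Labeled epoch tibble from [trim_and_label()].
#' @param metric `"enmo"` or `"mad"`.
#' @param discrimination One of `"standing"`, `"washing_pots"`,
#'   `"dusting"`, `"sweeping"`, `"walk"`.
#' @param granularity `"participant_activity_mean"` (default) or
#'   `"epoch"`.
#' @return Tibble `value_mg`, `label` (0 sedentary / 1 activity),
#'   `participant_id`, `activity_id`, with the choices stored as
#'   attributes `metric`, `discrimination`, `granularity`.
#' @export
build_discrimination <- function(set,
                                 metric = c("enmo", "mad"),
                                 discrimination = c("standing", "washing_pots",
                                                    "dusting", "sweeping", "walk"),
                                 granularity = c("participant_activity_mean", "epoch")) {
  metric <- match.arg(metric)
  discrimination <- match.arg(discrimination)
  granularity <- match.arg(granularity)
  if (nrow(set) == 0L) {
    abort("Labeled epoch set is empty.", class = "accelcut_precondition_error")
  }
  target <- discrimination_ids()[[discrimination]]
  value_col <- paste0(metric, "_mg")
  dat <- set |>
    dplyr::filter(.data$activity_id %in% c(sedentary_ids(), target)) |>
    dplyr::mutate(label = as.integer(.data$activity_id == target),
                  value_mg = .data[[value_col]])
  if (granularity == "participant_activity_mean") {
    dat <- dat |>
      dplyr::group_by(.data$participant_id, .data$activity_id, .data$label) |>
      dplyr::summarise(value_mg = mean(.data$value_mg), .groups = "drop")
  }
  for (cls in 0:1) {
    if (sum(dat$label == cls) == 0L) {
      abort(sprintf("Discrimination '%s': class %d has no observations.",
                    discrimination, cls), class = "accelcut_validation_error")
    }
  }
  out <- tibble::tibble(value_mg = dat$value_mg, label = dat$label,
                        participant_id = dat$participant_id,
                        activity_id = dat$activity_id)
  attr(out, "metric") <- metric
  attr(out, "discrimination") <- discrimination
  attr(out, "granularity") <- granularity
  out
}

#' Mean and standard error of a metric by activity group
#'
#' Reproduces the shape of the descriptive tables: each participant
#' first contributes one value per group (sedentary behaviours pool
#' activities 1-11 within participant before averaging across
#' participants), then the mean and between-participant standard error
#' are taken across participants. With a single participant the SE is
#' undefined and reported as `NA`.
#'
#' @inheritParams build_discrimination
#' @return Tibble `group`, `mean_mg`, `se_mg`, `n_participants`.
#' @export
summarize_by_activity <- function(set, metric = c("enmo", "mad")) {
  metric <- match.arg(metric)
  if (nrow(set) == 0L) {
    abort("Labeled epoch set is empty.", class = "accelcut_precondition_error")
  }
  value_col <- paste0(metric, "_mg")
  labels <- protocol_activities()
  grouped <- set |>
    dplyr::mutate(group = ifelse(.data$activity_id %in% sedentary_ids(),
                                 "sedentary behaviours",
                                 labels$label[.data$activity_id]),
                  value = .data[[value_col]])
  per_participant <- grouped |>
    dplyr::group_by(.data$group, .data$participant_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  per_participant |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_mg = mean(.data$value),
      se_mg = if (dplyr::n() > 1L) stats::sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      n_participants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$group, c("sedentary behaviours", labels$label[12:16])))
}
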