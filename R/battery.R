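#' Derive and validate thresholds for every stratum
#'
#' Runs the full inferential pipeline for each metric x brand x
#' placement stratum present in the labeled data and each of the five
#' discriminations: assemble the discrimination dataset, fit the
#' univariate logistic model, derive the Youden-optimal threshold from
#' the ROC curve on the raw metric values, compute the apparent AUROC
#' (DeLong CI) and the pooled leave-one-out cross-validated AUROC. With
#' both brands, both placements and both metrics present this yields
#' 2 x 2 x 2 x 5 = 40 threshold reports. Strata or discriminations with
#' a missing class are skipped with a warning.
#'
#' Whenever the fitted slope is positive, the AUROC of the logistic
#' predicted probabilities must equal the AUROC of the raw values (rank
#' invariance); this is asserted on every run and a violation raises a
#' warning naming the stratum.
#'
#' @param labeled Labeled epoch tibble from [trim_and_label()] (possibly
#'   several participants/recordings bound together).
#' @param metrics Metrics to run (default both `"enmo"` and `"mad"`).
#' @param granularity Observation granularity passed to
#'   [build_discrimination()].
#' @param loocv_unit Fold unit for [loocv_auroc()].
#' @param conf_level Confidence level for AUROC intervals.
#' @return Tibble of class `threshold_battery`, one row per report:
#'   metric, brand, placement, discrimination, threshold_mg,
#'   sensitivity, specificity, auroc (+ CI), loocv_auroc (+ CI), n_pos,
#'   n_neg, converged.
#' @export
run_threshold_battery <- function(labeled,
                                  metrics = c("enmo", "mad"),
                                  granularity = c("participant_activity_mean", "epoch"),
                                  loocv_unit = c("observation", "participant"),
                                  conf_level = 0.95) {
  granularity <- match.arg(granularity)
  loocv_unit <- match.arg(loocv_unit)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (nrow(labeled) == 0L) {
    abort("No labeled epochs.", class = "accelcut_precondition_error")
  }
  strata <- labeled |> dplyr::distinct(.data$brand, .data$placement)
  grid <- tidyr::expand_grid(strata, metric = metrics,
                             discrimination = names(discrimination_ids()))
  rows <- purrr::pmap(grid, function(brand, placement, metric, discrimination) {
    sub <- labeled[labeled$brand == brand & labeled$placement == placement, ,
                   drop = FALSE]
    ds <- tryCatch(
      build_discrimination(sub, metric = metric, discrimination = discrimination,
                           granularity = granularity),
      error = function(e) {
        warn(sprintf("Skipping %s/%s/%s/%s: %s", metric, brand, placement,
                     discrimination, conditionMessage(e)))
        NULL
      })
    if (is.null(ds)) return(NULL)
    fit <- fit_logistic(ds)
    probs <- predict(fit, ds$value_mg)
    roc <- roc_curve(ds)
    opt <- suppressWarnings(optimal_threshold(roc))
    a_raw <- auroc(ds, conf_level = conf_level)
    if (fit$slope > 0) {
      a_prob <- auroc(ds, scores = probs, conf_level = conf_level)
      if (abs(a_prob$auroc - a_raw$auroc) > 1e-12) {
        warn(sprintf("Rank-invariance violated for %s/%s/%s/%s (%.15f vs %.15f).",
                     metric, brand, placement, discrimination,
                     a_prob$auroc, a_raw$auroc))
      }
    }
    cv <- loocv_auroc(ds, unit = loocv_unit, conf_level = conf_level)
    tibble::tibble(
      metric = metric, brand = brand, placement = placement,
      discrimination = discrimination,
      threshold_mg = opt$threshold_mg,
      sensitivity = opt$sensitivity, specificity = opt$specificity,
      auroc = a_raw$auroc, auroc_lo = a_raw$ci_lo, auroc_hi = a_raw$ci_hi,
      loocv_auroc = cv$loocv_auroc, loocv_lo = cv$ci_lo, loocv_hi = cv$ci_hi,
      n_pos = a_raw$n_pos, n_neg = a_raw$n_neg,
      converged = fit$converged
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("threshold_battery", class(out))
  attr(out, "granularity") <- granularity
  attr(out, "loocv_unit") <- loocv_unit
  out
}

#' Brand comparison table for every activity group
#'
#' For each placement, metric and activity group (sedentary pooled,
#' each upright activity separately), compares per-participant means
#' between the two brands with an unpaired t-test — the companion of the
#' descriptive summary tables.
#'
#' @inheritParams run_threshold_battery
#' @param variant t-test variant, see [compare_brands()].
#' @return Tibble: placement, metric, group, brand means and the t-test
#'   columns of [compare_brands()].
#' @export
brand_comparison_table <- function(labeled, metrics = c("enmo", "mad"),
                                   variant = c("student", "welch")) {
  variant <- match.arg(variant)
  metrics <- match.arg(metrics, several.ok = TRUE)
  brands <- sort(unique(labeled$brand))
  if (length(brands) != 2L) {
    abort("Brand comparison needs exactly two brands in the labeled data.",
          class = "accelcut_precondition_error")
  }
  grid <- tidyr::expand_grid(placement = unique(labeled$placement), metric = metrics)
  purrr::pmap(grid, function(placement, metric) {
    value_col <- paste0(metric, "_mg")
    sub <- labeled[labeled$placement == placement, , drop = FALSE]
    per <- sub |>
      dplyr::mutate(group = ifelse(.data$activity_id %in% sedentary_ids(),
                                   "sedentary behaviours",
                                   protocol_activities()$label[.data$activity_id])) |>
      dplyr::group_by(.data$group, .data$brand, .data$participant_id) |>
      dplyr::summarise(value = mean(.data[[value_col]]), .groups = "drop")
    purrr::map(unique(per$group), function(g) {
      a <- per$value[per$group == g & per$brand == brands[1]]
      b <- per$value[per$group == g & per$brand == brands[2]]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      res <- compare_brands(a, b, variant = variant)
      dplyr::bind_cols(tibble::tibble(placement = placement, metric = metric,
                                      group = g, brand_a = brands[1],
                                      brand_b = brands[2]), res)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
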