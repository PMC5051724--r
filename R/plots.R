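#' Plot a ROC curve
#'
#' @param object An `accel_roc` tibble from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot: 1 - specificity against sensitivity with the
#'   chance diagonal.
#' @export
autoplot.accel_roc <- function(object, ...) {
  dat <- dplyr::arrange(tibble::as_tibble(object), dplyr::desc(.data$threshold))
  ggplot2::ggplot(dat, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot a threshold battery
#'
#' Apparent and cross-validated AUROC per discrimination, with DeLong
#' intervals, faceted by metric and placement, coloured by brand.
#'
#' @param object A `threshold_battery` tibble from
#'   [run_threshold_battery()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_battery <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(discrimination = factor(.data$discrimination,
                                          levels = names(discrimination_ids())))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$discrimination, y = .data$auroc,
                                    colour = .data$brand)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$auroc_lo, ymax = .data$auroc_hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$loocv_auroc), shape = 1,
                        position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_grid(metric ~ placement) +
    ggplot2::labs(x = NULL, y = "AUROC (filled: apparent, open: LOOCV)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot activity-group metric means
#'
#' Column plot of the per-group means with between-participant standard
#' error bars, as produced by [summarize_by_activity()].
#'
#' @param summary Tibble from [summarize_by_activity()].
#' @return A ggplot.
#' @export
plot_activity_means <- function(summary) {
  dat <- dplyr::mutate(summary, group = factor(.data$group, levels = .data$group))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$mean_mg)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_mg - .data$se_mg,
                                        ymax = .data$mean_mg + .data$se_mg),
                           width = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Mean epoch metric (mg)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
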