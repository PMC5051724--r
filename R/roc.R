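#' ROC curve for one discrimination
#'
#' Classification rule: `score >= threshold` predicts the positive
#' class. One point is produced per distinct observed score, plus the
#' two degenerate endpoints (threshold `-Inf`: sensitivity 1 /
#' specificity 0; `Inf`: sensitivity 0 / specificity 1).
#'
#' @param ds Discrimination tibble from [build_discrimination()] (or any
#'   data frame with `value_mg` and binary `label`).
#' @param scores Per-observation scores; defaults to the raw metric
#'   values `ds$value_mg`.
#' @return Tibble of class `accel_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`, ordered by threshold.
#' @export
roc_curve <- function(ds, scores = NULL) {
  scores <- scores %||% ds$value_mg
  y <- ds$label
  check_two_classes(y)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  out <- tibble::tibble(
    threshold = c(-Inf, thr, Inf),
    sensitivity = c(1, sens, 0),
    specificity = c(0, spec, 1)
  )
  class(out) <- c("accel_roc", class(out))
  out
}

check_two_classes <- function(y) {
  if (sum(y == 1) == 0L || sum(y == 0) == 0L) {
    abort("Both classes must be present.", class = "accelcut_precondition_error")
  }
  invisible(TRUE)
}

#' Optimal threshold on a ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the finite
#' ROC points. Ties are broken by higher sensitivity, then by lower
#' threshold. If no point achieves J > 0 the scores are
#' anti-discriminating (or pure noise) and a warning is raised.
#'
#' @param roc An `accel_roc` tibble from [roc_curve()].
#' @param criterion Threshold criterion; only `"youden"` is implemented.
#' @return One-row tibble `threshold_mg`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
optimal_threshold <- function(roc, criterion = c("youden")) {
  criterion <- match.arg(criterion)
  finite <- roc[is.finite(roc$threshold), , drop = FALSE]
  if (nrow(finite) < 2L) {
    abort("Degenerate ROC: scores take a single value, no threshold separates anything.",
          class = "accelcut_validation_error")
  }
  j <- finite$sensitivity + finite$specificity - 1
  best <- which(j == max(j))
  best <- best[order(-finite$sensitivity[best], finite$threshold[best])][1]
  if (max(j) <= 0) {
    warn("No threshold achieves Youden's J > 0: scores do not discriminate in the expected direction.")
  }
  tibble::tibble(threshold_mg = finite$threshold[best],
                 sensitivity = finite$sensitivity[best],
                 specificity = finite$specificity[best],
                 youden_j = j[best])
}

#' AUROC with DeLong confidence interval
#'
#' Area under the ROC curve by the Mann-Whitney pair-counting estimator
#' (ties credited 0.5): the probability that a random positive scores
#' above a random negative. The confidence interval uses the DeLong
#' variance estimator with a normal approximation, clamped to `[0, 1]`.
#'
#' @inheritParams roc_curve
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble `auroc`, `se`, `ci_lo`, `ci_hi`, `n_pos`,
#'   `n_neg`.
#' @export
auroc <- function(ds, scores = NULL, conf_level = 0.95) {
  scores <- scores %||% ds$value_mg
  y <- ds$label
  check_two_classes(y)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  m <- length(pos)
  n <- length(neg)
  # midrank identity for the pair-counting placements
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  auc <- mean(v10)
  se <- if (m > 1L && n > 1L) sqrt(var(v10) / m + var(v01) / n) else NA_real_
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    auroc = auc, se = se,
    ci_lo = if (is.na(se)) NA_real_ else max(0, auc - zq * se),
    ci_hi = if (is.na(se)) NA_real_ else min(1, auc + zq * se),
    n_pos = m, n_neg = n
  )
}

#' Leave-one-out cross-validated AUROC
#'
#' For each held-out unit a logistic model is refitted on the remaining
#' observations and the held-out predicted probabilities are recorded;
#' the out-of-fold predictions are pooled over all folds and a single
#' AUROC (with DeLong CI) is computed on the pooled set. `unit =
#' "observation"` leaves one observation out per fold (n folds of n - 1
#' training observations); `unit = "participant"` leaves all of one
#' participant's observations out, the subject-independent variant. A
#' training fold reduced to a single class falls back to predicting the
#' fold prevalence for its held-out unit (counted in `n_fallback_folds`).
#'
#' @inheritParams auroc
#' @param unit `"observation"` (default) or `"participant"`.
#' @return One-row tibble `loocv_auroc`, `se`, `ci_lo`, `ci_hi`,
#'   `n_folds`, `n_fallback_folds`.
#' @export
loocv_auroc <- function(ds, unit = c("observation", "participant"),
                        conf_level = 0.95) {
  unit <- match.arg(unit)
  y <- ds$label
  check_two_classes(y)
  fold_of <- if (unit == "observation") {
    seq_len(nrow(ds))
  } else {
    match(ds$participant_id, unique(ds$participant_id))
  }
  n_folds <- max(fold_of)
  if (n_folds < 3L) {
    abort("LOOCV needs at least 3 folds.", class = "accelcut_precondition_error")
  }
  preds <- numeric(nrow(ds))
  n_fallback <- 0L
  for (f in seq_len(n_folds)) {
    test <- fold_of == f
    train <- ds[!test, , drop = FALSE]
    if (length(unique(train$label)) < 2L || sum(train$label == 0) < 2L ||
        sum(train$label == 1) < 2L) {
      preds[test] <- mean(train$label)
      n_fallback <- n_fallback + 1L
    } else {
      fit <- fit_logistic(train)
      preds[test] <- predict(fit, ds$value_mg[test])
    }
  }
  a <- auroc(ds, scores = preds, conf_level = conf_level)
  tibble::tibble(loocv_auroc = a$auroc, se = a$se,
                 ci_lo = a$ci_lo, ci_hi = a$ci_hi,
                 n_folds = n_folds, n_fallback_folds = n_fallback)
}

#' Compare per-participant means between device brands
#'
#' Unpaired two-sample t-test of one activity group's per-participant
#' metric means between two accelerometer brands. The default
#' `"student"` variant pools variances; `"welch"` does not. Two
#' constant, equal groups carry no evidence of a difference and return
#' p = 1 with `flag = "zero_variance"`.
#'
#' @param values_a,values_b Numeric vectors of per-participant means for
#'   the two brands (each of length >= 2).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return One-row tibble `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `variant`, `flag`.
#' @export
compare_brands <- function(values_a, values_b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort("Each group needs at least 2 values.", class = "accelcut_precondition_error")
  }
  flag <- NA_character_
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(tibble::tibble(statistic = 0, df = NA_real_, p_value = 1,
                            mean_a = mean(values_a), mean_b = mean(values_b),
                            variant = variant, flag = "zero_variance"))
    }
    return(tibble::tibble(statistic = sign(mean(values_a) - mean(values_b)) * Inf,
                          df = NA_real_, p_value = 0,
                          mean_a = mean(values_a), mean_b = mean(values_b),
                          variant = variant, flag = "zero_variance"))
  }
  tt <- t.test(values_a, values_b, var.equal = (variant == "student"))
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_a = mean(values_a),
                 mean_b = mean(values_b), variant = variant, flag = flag)
}
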