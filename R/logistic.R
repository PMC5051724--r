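#' Univariate logistic regression for one discrimination
#'
#' Maximum-likelihood fit of `P(label = 1) = plogis(a + b * value_mg)`
#' by iteratively re-weighted least squares on a standardized predictor.
#' Complete separation (diverging slope beyond 1e4 per mg, or failure to
#' reach a gradient norm below 1e-8 within `max_iter` IRLS steps) trips
#' a ridge-stabilized refit (penalty 1e-6 on the standardized slope) and
#' the result is flagged `converged = FALSE`, `fallback = TRUE`.
#'
#' @param ds Discrimination tibble from [build_discrimination()] — or any
#'   data frame with numeric `value_mg` and binary `label` columns.
#' @param max_iter IRLS iteration cap (default 100).
#' @param ridge Slope penalty used by the separation fallback.
#' @return Object of class `accel_logit`: intercept and slope on the mg
#'   scale, `converged`, `fallback`, `n_iter`, `log_likelihood`,
#'   standard errors, and the centring/scaling constants.
#' @export
fit_logistic <- function(ds, max_iter = 100, ridge = 1e-6) {
  x <- ds$value_mg
  y <- ds$label
  if (length(unique(y[!is.na(y)])) < 2L) {
    abort("Both classes must be present to fit a logistic model.",
          class = "accelcut_precondition_error")
  }
  if (sum(y == 0) < 2L || sum(y == 1) < 2L) {
    abort("Each class needs at least 2 observations.",
          class = "accelcut_precondition_error")
  }
  ctr <- mean(x)
  scl <- stats::sd(x)
  if (!is.finite(scl) || scl == 0) scl <- 1
  z <- (x - ctr) / scl
  X <- cbind(1, z)
  # with one predictor, complete separation is directly visible in the data
  separated <- min(x[y == 1]) > max(x[y == 0]) || max(x[y == 1]) < min(x[y == 0])
  grad_norm <- NA_real_
  n_iter <- 0L
  beta <- c(0, 0)
  if (!separated) {
    fit <- suppressWarnings(
      glm.fit(X, y, family = binomial(),
              control = list(epsilon = 1e-12, maxit = max_iter))
    )
    beta <- fit$coefficients
    n_iter <- fit$iter
    # Newton polish: IRLS stops on deviance change, the convergence
    # contract here is a gradient norm below 1e-8
    for (k in seq_len(25L)) {
      p <- as.vector(plogis(X %*% beta))
      g <- crossprod(X, y - p)
      grad_norm <- max(abs(g))
      if (!is.finite(grad_norm) || grad_norm < 1e-10) break
      w <- pmax(p * (1 - p), 1e-12)
      beta <- beta + as.vector(solve(crossprod(X * sqrt(w)), g))
      n_iter <- n_iter + 1L
    }
    p <- as.vector(plogis(X %*% beta))
    grad_norm <- max(abs(crossprod(X, y - p)))
    separated <- !all(is.finite(beta)) || abs(beta[2] / scl) > 1e4 ||
      grad_norm >= 1e-8 || n_iter > max_iter
  }
  fallback <- FALSE
  if (separated) {
    rf <- ridge_logit(X, y, lambda = ridge, max_iter = max_iter)
    beta <- rf$beta
    n_iter <- rf$n_iter
    fallback <- TRUE
  }
  p <- as.vector(plogis(X %*% beta))
  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  if (fallback) info <- info + diag(c(0, ridge))
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  # back-transform to the mg scale
  slope <- beta[2] / scl
  intercept <- beta[1] - beta[2] * ctr / scl
  se_slope <- sqrt(vc[2, 2]) / scl
  se_intercept <- sqrt(vc[1, 1] + (ctr / scl)^2 * vc[2, 2] -
                         2 * (ctr / scl) * vc[1, 2])
  eps <- 1e-12
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  structure(list(intercept = unname(intercept), slope = unname(slope),
                 se_intercept = unname(se_intercept), se_slope = unname(se_slope),
                 converged = !separated, fallback = fallback,
                 n_iter = as.integer(n_iter), log_likelihood = ll,
                 gradient_norm = unname(grad_norm),
                 n = length(y), n_pos = sum(y == 1), n_neg = sum(y == 0),
                 center = ctr, scale = scl),
            class = "accel_logit")
}

# Ridge-penalized Newton iterations; penalty on the slope only, so the
# intercept stays unbiased toward prevalence.
ridge_logit <- function(X, y, lambda, max_iter = 100, tol = 1e-10) {
  beta <- c(0, 0)
  pen <- diag(c(0, lambda))
  it <- 0L
  for (it in seq_len(max_iter)) {
    p <- as.vector(plogis(X %*% beta))
    w <- pmax(p * (1 - p), 1e-10)
    grad <- crossprod(X, y - p) - pen %*% beta
    hess <- crossprod(X * sqrt(w)) + pen
    step <- solve(hess, grad)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, n_iter = it)
}

#' @export
print.accel_logit <- function(x, ...) {
  cat(sprintf("<accel_logit> logit(p) = %.4f + %.5f * value_mg  (n=%d: %d pos / %d neg)\n",
              x$intercept, x$slope, x$n, x$n_pos, x$n_neg))
  if (!x$converged) {
    cat("  separation detected: ridge-stabilized fallback fit, converged = FALSE\n")
  }
  invisible(x)
}

#' Predicted probabilities from a logistic fit
#'
#' @param object An `accel_logit` fit.
#' @param newdata Numeric vector of metric values (mg), or a data frame
#'   with a `value_mg` column.
#' @param ... Unused.
#' @return Vector of predicted probabilities of the positive class.
#' @export
predict.accel_logit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$value_mg else newdata
  plogis(object$intercept + object$slope * x)
}

#' @export
tidy.accel_logit <- function(x, ...) {
  est <- c(x$intercept, x$slope)
  se <- c(x$se_intercept, x$se_slope)
  z <- est / se
  tibble::tibble(
    term = c("(Intercept)", "value_mg"),
    estimate = est, std.error = se, statistic = z,
    p.value = 2 * stats::pnorm(-abs(z))
  )
}

#' @export
glance.accel_logit <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood, n_iter = x$n_iter,
                 converged = x$converged, fallback = x$fallback,
                 n = x$n, n_pos = x$n_pos, n_neg = x$n_neg)
}
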