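#' Ordinary least-squares calibration with a common y-uncertainty
#'
#' Fits the linear calibration `LWP = m * NDVI + c` assuming all the error
#' lives in y and is homoscedastic, the textbook error-analysis treatment.
#' The common uncertainty is estimated from the residuals,
#' `sigma_y = sqrt(sum(r_i^2) / (n - 2))`, and propagated into the
#' coefficients: with `Delta = n * sum(x^2) - sum(x)^2`,
#' `dm = sigma_y * sqrt(n / Delta)` and `dc = sigma_y * sqrt(sum(x^2) / Delta)`.
#' These closed forms coincide with the standard errors of an unweighted
#' linear model fit, but are computed directly so the propagation chain is
#' explicit.
#'
#' The maximum relative error of a predicted LWP at the dataset means is
#' attached as `rel_pred_error` (see [relative_prediction_error()]).
#'
#' @param data A [regression_dataset()] with at least 3 points; the
#'   uncertainty columns are ignored by this method.
#' @return A `fit_result` object: list with `method = "OLS"`, coefficients
#'   `m`, `c`, their uncertainties `dm`, `dc`, `n`, `sigma_y`, `r_squared`,
#'   `p_slope` (two-sided t test of slope = 0 on n - 2 df), `x_mean`,
#'   `y_mean`, `rel_pred_error` and the dataset `label`.
#' @examples
#' d <- regression_dataset(c(0, 1, 2), c(0, 1, 3))
#' f <- fit_ols(d)
#' c(f$m, f$c, f$dm, f$dc)
#' @export
fit_ols <- function(data) {
  stopifnot(inherits(data, "regression_dataset"))
  x <- data$x; y <- data$y
  n <- length(x)
  if (n < 3)
    stop("OLS with coefficient uncertainties needs at least 3 points")
  sx <- sum(x); sxx <- sum(x^2)
  delta <- n * sxx - sx^2
  if (delta <= 0 || isTRUE(all.equal(stats::var(x), 0)))
    stop("all x values are (nearly) equal: slope is not identifiable")
  sy <- sum(y); sxy <- sum(x * y)
  m <- (n * sxy - sx * sy) / delta
  c0 <- (sxx * sy - sx * sxy) / delta
  r <- y - m * x - c0
  sigma_y <- sqrt(sum(r^2) / (n - 2))
  dm <- sigma_y * sqrt(n / delta)
  dc <- sigma_y * sqrt(sxx / delta)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(r^2) / ss_tot else 1
  p_slope <- if (dm > 0) 2 * stats::pt(-abs(m / dm), df = n - 2) else 0
  fit <- structure(list(
    method = "OLS", m = m, c = c0, dm = dm, dc = dc, n = n,
    sigma_y = sigma_y, r_squared = r2, p_slope = p_slope,
    x_mean = mean(x), y_mean = mean(y),
    label = attr(data, "label")
  ), class = "fit_result")
  fit$rel_pred_error <- if (fit$y_mean != 0)
    relative_prediction_error(fit) else NA_real_
  fit
}

#' Maximum relative error of a predicted LWP
#'
#' Propagates the coefficient uncertainties of a linear calibration into an
#' upper bound on the relative error of the predicted y at a reference x:
#' `(|x| * dm + dc) / |y|`. By default the bound is evaluated at the dataset
#' means (the reference point used in the published summary tables); pass
#' `x_mean`/`y_mean` for a pointwise bound elsewhere.
#'
#' @param fit A `fit_result` from [fit_ols()] or [fit_wls()].
#' @param x_mean Reference NDVI; defaults to the fitted dataset's mean x.
#' @param y_mean Reference LWP (MPa, nonzero); defaults to the mean y.
#' @return The dimensionless relative error bound.
#' @export
relative_prediction_error <- function(fit, x_mean = fit$x_mean,
                                      y_mean = fit$y_mean) {
  stopifnot(inherits(fit, "fit_result"))
  if (is.null(y_mean) || is.na(y_mean) || y_mean == 0)
    stop("reference y must be nonzero")
  (abs(x_mean) * fit$dm + fit$dc) / abs(y_mean)
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit '%s' (n = %d)\n", x$method, x$label, x$n))
  cat(sprintf("  m = %s (dm = %s)   [MPa per NDVI unit]\n",
              format(x$m, digits = digits), format(x$dm, digits = digits)))
  cat(sprintf("  c = %s (dc = %s)   [MPa]\n",
              format(x$c, digits = digits), format(x$dc, digits = digits)))
  if (!is.null(x$r_squared) && !is.na(x$r_squared %||% NA))
    cat(sprintf("  R^2 = %s, p(slope) = %s\n",
                format(x$r_squared, digits = digits),
                format(x$p_slope, digits = digits)))
  if (!is.null(x$s_weighted))
    cat(sprintf("  weighted S = %s (%d iterations, eval at %s points)\n",
                format(x$s_weighted, digits = digits), x$iterations, x$eval_at))
  if (!is.null(x$rel_pred_error) && !is.na(x$rel_pred_error))
    cat(sprintf("  max relative prediction error at means = %s\n",
                format(x$rel_pred_error, digits = digits)))
  invisible(x)
}
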