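#' Percent errors of the fitted coefficients
#'
#' The relative sizes of the coefficient uncertainties,
#' `100 * dm / |m|` and `100 * dc / |c|`, the headline comparison between
#' the two fitting methods. Values are returned at full precision; integer
#' rounding is applied only in the display layer ([write_results_table()]).
#'
#' @param fit A `fit_result` with nonzero `m` and `c`.
#' @return Named numeric `c(pct_dm, pct_dc)`.
#' @examples
#' \dontrun{percent_coefficient_errors(fit_wls(d))}
#' @export
percent_coefficient_errors <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$m == 0 || fit$c == 0)
    stop("percent errors undefined for a zero coefficient")
  c(pct_dm = 100 * fit$dm / abs(fit$m),
    pct_dc = 100 * fit$dc / abs(fit$c))
}

#' Measurement uncertainty relative to the measurement range
#'
#' A signal-to-noise diagnostic of one coordinate: the typical per-group
#' uncertainty as a percentage of the span of the group means,
#' `100 * central(delta) / (max(means) - min(means))`. The central summary
#' of the per-group uncertainties is their arithmetic mean by default;
#' median and pooled (root-mean-square) summaries are selectable.
#'
#' @param uncertainties Per-group uncertainties (SEMs), >= 0.
#' @param means Per-group means (>= 2 values spanning a nonzero range).
#' @param summary `"mean"` (default), `"median"` or `"pooled"`.
#' @return Percentage, or `NA` with a warning when the range is zero.
#' @examples
#' uncertainty_range_ratio(c(0.02, 0.04), c(0.6, 0.9))  # 10
#' @export
uncertainty_range_ratio <- function(uncertainties, means,
                                    summary = c("mean", "median", "pooled")) {
  summary <- match.arg(summary)
  if (length(means) < 2) stop("need at least 2 group means")
  R <- max(means) - min(means)
  if (R == 0) {
    warning("zero measurement range: ratio undefined")
    return(NA_real_)
  }
  d <- switch(summary,
              mean = mean(uncertainties),
              median = stats::median(uncertainties),
              pooled = sqrt(mean(uncertainties^2)))
  100 * d / R
}

#' Uncertainty summary of one fitted dataset
#'
#' Bundles the percent coefficient errors, the uncertainty-to-range ratios
#' of both coordinates, and the relative prediction error, for one fit.
#'
#' @param fit A `fit_result`.
#' @param data The fitted [regression_dataset()] (for the range ratios).
#' @param summary Central summary passed to [uncertainty_range_ratio()].
#' @return An `uncertainty_summary` list.
#' @export
uncertainty_summary <- function(fit, data, summary = "mean") {
  pct <- percent_coefficient_errors(fit)
  ndvi_ratio <- if (anyNA(data$dx)) NA_real_ else
    uncertainty_range_ratio(data$dx, data$x, summary)
  lwp_ratio <- uncertainty_range_ratio(data$dy, data$y, summary)
  structure(list(label = fit$label, method = fit$method,
                 pct_dm = unname(pct["pct_dm"]), pct_dc = unname(pct["pct_dc"]),
                 ndvi_ratio = ndvi_ratio, lwp_ratio = lwp_ratio,
                 rel_pred_error = fit$rel_pred_error),
            class = "uncertainty_summary")
}

#' @export
print.uncertainty_summary <- function(x, ...) {
  cat(sprintf("Uncertainty summary '%s' (%s)\n", x$label, x$method))
  cat(sprintf("  dm/m = %.0f%%, dc/c = %.0f%%\n", x$pct_dm, x$pct_dc))
  cat(sprintf("  NDVI uncertainty/range = %s%%, LWP = %.1f%%\n",
              if (is.na(x$ndvi_ratio)) "-" else sprintf("%.1f", x$ndvi_ratio),
              x$lwp_ratio))
  cat(sprintf("  max relative prediction error = %.2f\n", x$rel_pred_error))
  invisible(x)
}

#' Consolidated results table over several fits
#'
#' Renders a list of fits in the published layout: label, method, n,
#' `m (dm)`, `c (dc)` formatted to two decimals, and the relative
#' prediction error. Full-precision numeric columns are kept alongside the
#' formatted ones; the CSV written to `file` carries both, and a plain
#' aligned-text rendering goes to `text_file` if given.
#'
#' @param fits List of `fit_result` objects (possibly empty).
#' @param file Optional CSV output path.
#' @param text_file Optional aligned-text output path.
#' @return The results data.frame, invisibly when writing.
#' @export
write_results_table <- function(fits, file = NULL, text_file = NULL) {
  cols <- c("label", "method", "n", "m_dm", "c_dc", "dY_Y",
            "m", "dm", "c", "dc", "rel_pred_error")
  if (length(fits) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
  } else {
    df <- do.call(rbind, lapply(fits, function(f) {
      data.frame(label = f$label, method = f$method, n = f$n,
                 m_dm = sprintf("%.2f (%.2f)", f$m, f$dm),
                 c_dc = sprintf("%.2f (%.2f)", f$c, f$dc),
                 dY_Y = sprintf("%.2f", f$rel_pred_error),
                 m = f$m, dm = f$dm, c = f$c, dc = f$dc,
                 rel_pred_error = f$rel_pred_error)
    }))
  }
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(text_file)) {
    txt <- utils::capture.output(print(
      df[, c("label", "method", "n", "m_dm", "c_dc", "dY_Y")],
      row.names = FALSE))
    writeLines(txt, text_file)
  }
  if (is.null(file) && is.null(text_file)) df else invisible(df)
}
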