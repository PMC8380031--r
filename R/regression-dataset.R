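#' Construct a paired regression dataset of NDVI and LWP group means
#'
#' The input contract of both fitters: one row per observation group, holding
#' the group mean NDVI (`x`), mean LWP in MPa (`y`), and their standard
#' errors of the mean (`dx`, `dy`). The four-column CSV layout written by
#' [write_regression_csv()] mirrors this ordering exactly.
#'
#' @param x Numeric vector of NDVI group means (dimensionless, in (-1, 1]).
#' @param y Numeric vector of LWP group means (MPa; conventionally <= 0).
#' @param dx Numeric vector of NDVI SEMs (>= 0), or `NULL`/`NA` when the
#'   scans were unreplicated. A dataset with any missing `dx` is flagged
#'   OLS-only: the bivariate fitter refuses it unless the user supplies a
#'   substitute uncertainty.
#' @param dy Numeric vector of LWP SEMs (MPa, >= 0).
#' @param label Character label carried into fit results and report tables.
#' @return An object of class `regression_dataset`: a `data.frame` with
#'   columns `x`, `y`, `dx`, `dy` and attributes `label` and `ols_only`.
#' @examples
#' d <- regression_dataset(x = c(0.6, 0.7, 0.8),
#'                         y = c(-2.2, -1.9, -1.5),
#'                         dx = c(0.01, 0.012, 0.009),
#'                         dy = c(0.06, 0.05, 0.07),
#'                         label = "example")
#' fit_ols(d)
#' @seealso [fit_ols()], [fit_wls()], [build_regression_dataset()]
#' @export
regression_dataset <- function(x, y, dx = NULL, dy = NULL, label = "dataset") {
  n <- length(x)
  if (length(y) != n)
    stop("`x` and `y` must have the same length")
  if (is.null(dx)) dx <- rep(NA_real_, n)
  if (is.null(dy)) dy <- rep(NA_real_, n)
  dx <- rep_len(as.numeric(dx), n)
  dy <- rep_len(as.numeric(dy), n)
  if (any(stats::na.omit(dx) < 0) || any(stats::na.omit(dy) < 0))
    stop("uncertainties `dx` and `dy` must be non-negative")
  out <- data.frame(x = as.numeric(x), y = as.numeric(y), dx = dx, dy = dy)
  attr(out, "label") <- as.character(label)
  attr(out, "ols_only") <- anyNA(dx)
  class(out) <- c("regression_dataset", "data.frame")
  out
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf("Regression dataset '%s': %d points%s\n",
              attr(x, "label"), nrow(x),
              if (isTRUE(attr(x, "ols_only"))) " (OLS-only: NDVI SEM missing)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read or write the four-column aggregated dataset CSV
#'
#' The file layout holds exactly four data columns in the order NDVI mean,
#' LWP mean, NDVI SEM, LWP SEM, optionally preceded by label columns (any
#' column whose name is not one of `ndvi_mean`, `lwp_mean`, `ndvi_sem`,
#' `lwp_sem` is treated as a label).
#'
#' @param path File path.
#' @param label Dataset label; defaults to the file name on read.
#' @return `read_regression_csv()` returns a [regression_dataset()];
#'   `write_regression_csv()` returns `path` invisibly.
#' @export
read_regression_csv <- function(path, label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ndvi_mean", "lwp_mean", "ndvi_sem", "lwp_sem")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  regression_dataset(df$ndvi_mean, df$lwp_mean, df$ndvi_sem, df$lwp_sem,
                     label = label %||% basename(path))
}

#' @rdname read_regression_csv
#' @param data A [regression_dataset()].
#' @export
write_regression_csv <- function(data, path) {
  stopifnot(inherits(data, "regression_dataset"))
  out <- data.frame(ndvi_mean = data$x, lwp_mean = data$y,
                    ndvi_sem = data$dx, lwp_sem = data$dy)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
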