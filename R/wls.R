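#' Overall weight of one data point in the bivariate fit
#'
#' Merges the two coordinate weights of a point, `wx = 1/dx^2` and
#' `wy = 1/dy^2`, into the single weight that multiplies its squared
#' residual at slope `m`:
#' \deqn{Z = \frac{w_x w_y}{m^2 w_y + w_x}.}
#' As `wx` grows (x error vanishing) `Z` tends to `wy`, recovering ordinary
#' y-weighting; symmetrically for `wy`.
#'
#' @param wx,wy Positive coordinate weights (may be vectors).
#' @param m Slope at which the weight is evaluated.
#' @return The overall weights, same length as `wx`.
#' @export
overall_weight <- function(wx, wy, m) {
  if (any(wx <= 0) || any(wy <= 0))
    stop("weights must be positive")
  wx * wy / (m^2 * wy + wx)
}

#' Residual of the least-squares cubic in the slope
#'
#' The weighted sum of squares `S = sum(Z_i * (y_i - m x_i - c)^2)` is
#' minimised in the slope by a root of a cubic-shaped estimating equation
#' whose coefficients themselves depend on `m` through the overall weights
#' `Z_i` and the weighted-centroid deviations
#' `U_i = x_i - sum(Z x)/sum(Z)`, `V_i = y_i - sum(Z y)/sum(Z)`:
#' \deqn{m^3 \sum \frac{Z_i^2 U_i^2}{w_{x,i}}
#'  - 2 m^2 \sum \frac{Z_i^2 U_i V_i}{w_{x,i}}
#'  - m \left[\sum Z_i U_i^2 - \sum \frac{Z_i^2 V_i^2}{w_{x,i}}\right]
#'  + \sum Z_i U_i V_i = 0.}
#' Because `Z`, `U`, `V` are recomputed at the trial slope, the equation is
#' only pseudo-cubic and must be solved iteratively; [fit_wls()] does so.
#' This evaluator is exported so the root structure can be inspected (e.g.
#' bracketing diagnostics).
#'
#' @param m Trial slope (scalar).
#' @param data A [regression_dataset()] with positive `dx`, `dy`.
#' @return The value of the estimating function at `m`; a root is a
#'   candidate best slope.
#' @export
cubic_residual <- function(m, data) {
  stopifnot(inherits(data, "regression_dataset"))
  if (nrow(data) < 3) stop("need at least 3 points")
  w <- .wls_weights(data)
  .wls_g(m, data$x, data$y, w$wx, w$wy)
}

.wls_g <- function(m, x, y, wx, wy) {
  Z <- wx * wy / (m^2 * wy + wx)
  sz <- sum(Z)
  U <- x - sum(Z * x) / sz
  V <- y - sum(Z * y) / sz
  m^3 * sum(Z^2 * U^2 / wx) - 2 * m^2 * sum(Z^2 * U * V / wx) -
    m * (sum(Z * U^2) - sum(Z^2 * V^2 / wx)) + sum(Z * U * V)
}

# Weighted S profiled over the intercept: at any m the minimising c is the
# Z-weighted centroid relation, so S becomes a function of m alone.
.wls_S <- function(m, x, y, wx, wy) {
  Z <- wx * wy / (m^2 * wy + wx)
  c0 <- (sum(Z * y) - m * sum(Z * x)) / sum(Z)
  sum(Z * (y - m * x - c0)^2)
}

# Replace zero uncertainties (infinite weights are ill-posed) by a floor:
# half the median positive uncertainty of the same coordinate, so a
# degenerate replicate draw gets a strong but finite weight rather than
# acting as an exact constraint. When a coordinate has no positive
# uncertainty at all (e.g. a noise-free study) the floor falls back to a
# tiny fraction of the coordinate range, which makes the weights equal and
# drops out of the solution.
.wls_weights <- function(data) {
  dx <- data$dx; dy <- data$dy
  if (anyNA(dx))
    stop("dataset is OLS-only (missing NDVI SEM); supply `dx` explicitly ",
         "or use fit_ols()")
  if (anyNA(dy)) stop("missing LWP SEM")
  floor_of <- function(d, coord) {
    pos <- d[d > 0]
    if (length(pos)) stats::median(pos) / 2
    else 1e-9 * max(diff(range(coord)), abs(coord), 1e-12)
  }
  if (any(dx <= 0)) {
    fl <- floor_of(dx, data$x)
    warning("zero NDVI uncertainty floored to ", format(fl))
    dx <- pmax(dx, fl)
  }
  if (any(dy <= 0)) {
    fl <- floor_of(dy, data$y)
    warning("zero LWP uncertainty floored to ", format(fl))
    dy <- pmax(dy, fl)
  }
  list(wx = 1 / dx^2, wy = 1 / dy^2)
}

# Root finder for the estimating function g(m): bracket around the seed,
# widening geometrically; locate every sign change on a grid across the
# bracket; polish each with uniroot; keep the root with the smallest S.
# Falls back to a dense S-scan plus local optimisation when no sign change
# is found (g can be rootless in pathological, near-vertical configurations).
.wls_solve <- function(x, y, wx, wy, m0, tol = 1e-12, max_iter = 200L) {
  g <- function(m) .wls_g(m, x, y, wx, wy)
  S <- function(m) .wls_S(m, x, y, wx, wy)
  # widen a bracket around the seed, scanning a grid across it each time so
  # interior sign changes are caught (the crossing region need not contain
  # the endpoints); widening is capped - beyond it g only has its
  # asymptotic tails and a direct S-scan is the reliable fallback
  h <- 0.5 * max(abs(m0), 1)
  flips <- integer(0)
  for (k in seq_len(24L)) {
    grid <- seq(m0 - h, m0 + h, length.out = 65L)
    gv <- vapply(grid, g, 0)
    flips <- which(gv[-1] * gv[-length(gv)] <= 0 &
                     is.finite(gv[-1]) & is.finite(gv[-length(gv)]))
    if (length(flips)) break
    h <- 2 * h
  }
  roots <- numeric(0)
  for (j in flips) {
    r <- tryCatch(
      stats::uniroot(g, c(grid[j], grid[j + 1]), tol = .Machine$double.eps^0.75),
      error = function(e) NULL)
    if (!is.null(r)) roots <- c(roots, r$root)
  }
  # direct search over the slope angle: S(tan(theta)) covers every slope
  # uniformly (including near-vertical ones far from the seed), so a local
  # stationary point near an attenuated seed cannot mask the global
  # minimum; the best scan interval is refined by golden-section search
  th <- seq(-pi / 2 + 1e-4, pi / 2 - 1e-4, length.out = 1801L)
  Sv <- vapply(tan(th), S, 0)
  i <- which.min(Sv)
  opt <- stats::optimize(function(t) S(tan(t)),
                         c(th[max(1, i - 1)], th[min(length(th), i + 1)]),
                         tol = .Machine$double.eps^0.5)
  roots <- c(roots, tan(opt$minimum))
  Sv <- vapply(roots, S, 0)
  best_root <- roots[which.min(Sv)]
  distinct <- abs(roots - best_root) > 1e-6 * (1 + abs(best_root))
  if (any(Sv[distinct] <= min(Sv) * (1 + 1e-6)))
    warning("multiple near-degenerate slope roots; returning the one with minimal S")
  # safeguarded Newton polish: only accept local steps that shrink |g|
  m <- best_root
  gm <- g(m)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    hstep <- 1e-7 * (1 + abs(m))
    dg <- (g(m + hstep) - g(m - hstep)) / (2 * hstep)
    if (!is.finite(dg) || dg == 0) break
    m_new <- m - gm / dg
    if (!is.finite(m_new) || abs(m_new - m) > 0.1 * (1 + abs(m))) break
    g_new <- g(m_new)
    if (!is.finite(g_new) || abs(g_new) >= abs(gm)) break
    conv <- abs(m_new - m) <= tol * (1 + abs(m_new))
    m <- m_new; gm <- g_new
    if (conv) break
  }
  list(m = m, iterations = iter)
}

#' Weighted least squares with measurement errors in both coordinates
#'
#' Fits `LWP = m * NDVI + c` when both coordinates carry known measurement
#' uncertainties, by minimising the doubly weighted sum of squares
#' `S = sum(wx_i (x_i - X_i)^2 + wy_i (y_i - Y_i)^2)` over lines and
#' adjusted points `(X_i, Y_i)` on the line, with weights the inverse
#' squared uncertainties. The slope solves the least-squares cubic (see
#' [cubic_residual()]) iteratively from an unweighted least-squares seed;
#' the intercept follows from the weighted centroid; each observed point is
#' then projected to its adjusted point, which lies exactly on the fitted
#' line.
#'
#' Coefficient variances use the scaled form
#' `dm^2 = S/(n-2) * sum[(dm/dy_i)^2 / wy_i + (dm/dx_i)^2 / wx_i]` (and the
#' analogous expression for `dc`), with the derivatives of the full solver
#' taken by central finite differences (step `1e-6 * delta_i` per
#' coordinate), evaluated either at the observed points or at the adjusted
#' points. The default is the adjusted points; the difference is small for
#' well-correlated data.
#'
#' @param data A [regression_dataset()] with `n >= 3` and positive
#'   uncertainties on both axes (zeros are floored with a warning; a
#'   dataset flagged OLS-only is rejected).
#' @param eval_at `"adjusted"` (default) or `"observed"`: where the
#'   coefficient-variance derivatives are evaluated.
#' @param se Compute `dm`/`dc`? Setting `FALSE` skips the finite-difference
#'   sweep (4n solver calls) when only the coefficients are needed.
#' @param tol Relative convergence tolerance on the slope.
#' @param max_iter Maximum polish iterations.
#' @return A `fit_result` with `method = "WLS"`, coefficients and
#'   uncertainties, `s_weighted` (S at the solution), `adjusted_points`
#'   (data.frame of `X`, `Y`), `iterations`, `eval_at`, `x_mean`, `y_mean`,
#'   and `rel_pred_error` at the dataset means.
#' @examples
#' d <- regression_dataset(x = c(0.6, 0.7, 0.8, 0.9),
#'                         y = c(-2.5, -2.0, -1.6, -1.1),
#'                         dx = rep(0.01, 4), dy = rep(0.08, 4))
#' fit_wls(d)
#' @export
fit_wls <- function(data, eval_at = c("adjusted", "observed"), se = TRUE,
                    tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(data, "regression_dataset"))
  eval_at <- match.arg(eval_at)
  n <- nrow(data)
  if (n < 3) stop("WLS needs at least 3 points")
  w <- .wls_weights(data)
  x <- data$x; y <- data$y; wx <- w$wx; wy <- w$wy

  m0 <- fit_ols(data)$m                      # unweighted seed
  sol <- .wls_solve(x, y, wx, wy, m0, tol = tol, max_iter = max_iter)
  m <- sol$m
  Z <- overall_weight(wx, wy, m)
  c0 <- (sum(Z * y) - m * sum(Z * x)) / sum(Z)
  r <- y - m * x - c0
  S <- sum(Z * r^2)
  X <- x + m * Z * r / wx                     # weighted projection onto the line
  Y <- y - Z * r / wy

  fit <- structure(list(
    method = "WLS", m = m, c = c0, dm = NA_real_, dc = NA_real_, n = n,
    s_weighted = S, adjusted_points = data.frame(X = X, Y = Y),
    iterations = sol$iterations, eval_at = eval_at,
    x_mean = mean(x), y_mean = mean(y),
    label = attr(data, "label")
  ), class = "fit_result")

  if (se) {
    pts <- if (eval_at == "adjusted") list(x = X, y = Y) else list(x = x, y = y)
    v <- .wls_var(pts$x, pts$y, wx, wy, m_hat = m, S = S, n = n)
    fit$dm <- v$dm; fit$dc <- v$dc
  }
  fit$rel_pred_error <- if (!is.na(fit$dm) && fit$y_mean != 0)
    relative_prediction_error(fit) else NA_real_
  fit
}

# Re-solve from a seed after a tiny coordinate perturbation: safeguarded
# Newton started at the unperturbed optimum (the perturbed root is nearby).
.wls_resolve <- function(x, y, wx, wy, m_seed) {
  g <- function(m) .wls_g(m, x, y, wx, wy)
  m <- m_seed
  for (iter in seq_len(60L)) {
    hstep <- 1e-7 * (1 + abs(m))
    dg <- (g(m + hstep) - g(m - hstep)) / (2 * hstep)
    if (!is.finite(dg) || dg == 0) break
    m_new <- m - g(m) / dg
    if (!is.finite(m_new) || abs(m_new - m_seed) > 0.5 * (1 + abs(m_seed))) {
      # wandered off: fall back to a full bracketed solve
      return(.wls_solve(x, y, wx, wy, m_seed)$m)
    }
    done <- abs(m_new - m) <= 1e-13 * (1 + abs(m_new))
    m <- m_new
    if (done) break
  }
  m
}

# Central finite differences of the (m, c) solution with respect to each
# coordinate; variance assembled with the S/(n-2) prefactor.
.wls_var <- function(x, y, wx, wy, m_hat, S, n) {
  c_of <- function(m, xx, yy) {
    Z <- wx * wy / (m^2 * wy + wx)
    (sum(Z * yy) - m * sum(Z * xx)) / sum(Z)
  }
  dm_dx <- dm_dy <- dc_dx <- dc_dy <- numeric(n)
  dxs <- 1 / sqrt(wx); dys <- 1 / sqrt(wy)
  # FD step: 1e-6 of the coordinate uncertainty, but never below a sane
  # fraction of the coordinate scale (floored uncertainties would otherwise
  # push the step under machine resolution and return noise, not a slope)
  sx <- max(diff(range(x)), 1e-6); sy <- max(diff(range(y)), 1e-6)
  for (i in seq_len(n)) {
    hx <- max(1e-6 * dxs[i], 1e-8 * sx)
    if (hx > 0) {
      xp <- x; xp[i] <- x[i] + hx
      xm <- x; xm[i] <- x[i] - hx
      mp <- .wls_resolve(xp, y, wx, wy, m_hat)
      mm <- .wls_resolve(xm, y, wx, wy, m_hat)
      dm_dx[i] <- (mp - mm) / (2 * hx)
      dc_dx[i] <- (c_of(mp, xp, y) - c_of(mm, xm, y)) / (2 * hx)
    }
    hy <- max(1e-6 * dys[i], 1e-8 * sy)
    if (hy > 0) {
      yp <- y; yp[i] <- y[i] + hy
      ym <- y; ym[i] <- y[i] - hy
      mp <- .wls_resolve(x, yp, wx, wy, m_hat)
      mm <- .wls_resolve(x, ym, wx, wy, m_hat)
      dm_dy[i] <- (mp - mm) / (2 * hy)
      dc_dy[i] <- (c_of(mp, x, yp) - c_of(mm, x, ym)) / (2 * hy)
    }
  }
  pref <- S / (n - 2)
  dm <- sqrt(pref * sum(dm_dy^2 / wy + dm_dx^2 / wx))
  dc <- sqrt(pref * sum(dc_dy^2 / wy + dc_dx^2 / wx))
  if (!is.finite(dm)) dm <- NA_real_
  if (!is.finite(dc)) dc <- NA_real_
  list(dm = dm, dc = dc)
}
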