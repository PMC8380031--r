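# Shared fixtures and independent oracles for the test suite.

# Random well-posed bivariate dataset with known generating line.
random_dataset <- function(seed, n = 8, m_range = c(-5, 5)) {
  set.seed(seed)
  m <- stats::runif(1, m_range[1], m_range[2])
  c0 <- stats::runif(1, -3, 3)
  x_true <- sort(stats::runif(n, 0, 1))
  dx <- stats::runif(n, 0.005, 0.05)
  dy <- stats::runif(n, 0.02, 0.2)
  x <- x_true + stats::rnorm(n, 0, dx)
  y <- m * x_true + c0 + stats::rnorm(n, 0, dy)
  structure(regression_dataset(x, y, dx, dy, label = paste0("rand", seed)),
            truth = c(m = m, c = c0))
}

# The classic 10-point bivariate benchmark with strongly varying weights
# in both coordinates.
york_benchmark <- function() {
  regression_dataset(
    x = c(0, 0.9, 1.8, 2.6, 3.3, 4.4, 5.2, 6.1, 6.5, 7.4),
    y = c(5.9, 5.4, 4.4, 4.6, 3.5, 3.7, 2.8, 2.8, 2.4, 1.5),
    dx = 1 / sqrt(c(1000, 1000, 500, 800, 200, 80, 60, 20, 1.8, 1)),
    dy = 1 / sqrt(c(1, 1.8, 4, 8, 20, 20, 70, 70, 100, 500)),
    label = "benchmark")
}

# Independent oracle: nested grid-search minimizer of the doubly weighted
# sum of squares, with the intercept profiled out through the weighted
# centroid. Never calls the package solver.
grid_search_wls <- function(data, lo = -50, hi = 50, refinements = 12) {
  wx <- 1 / data$dx^2
  wy <- 1 / data$dy^2
  S_of <- function(m) {
    Z <- wx * wy / (m^2 * wy + wx)
    c0 <- (sum(Z * data$y) - m * sum(Z * data$x)) / sum(Z)
    sum(Z * (data$y - m * data$x - c0)^2)
  }
  for (it in seq_len(refinements)) {
    grid <- seq(lo, hi, length.out = 401)
    Sv <- vapply(grid, S_of, 0)
    i <- which.min(Sv)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
  }
  m <- (lo + hi) / 2
  Z <- wx * wy / (m^2 * wy + wx)
  c0 <- (sum(Z * data$y) - m * sum(Z * data$x)) / sum(Z)
  list(m = m, c = c0, S = S_of(m))
}

# Closed-form orthogonal (major-axis) regression, the equal-weights limit.
major_axis_fit <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  m <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  list(m = m, c = mean(y) - m * mean(x))
}

# Analytic variance of the bivariate slope/intercept (adjusted-point form),
# scaled by S/(n-2); independent cross-check of the finite-difference path.
analytic_wls_se <- function(data, fit) {
  wx <- 1 / data$dx^2
  wy <- 1 / data$dy^2
  m <- fit$m
  Z <- wx * wy / (m^2 * wy + wx)
  X <- fit$adjusted_points$X
  xbar <- sum(Z * X) / sum(Z)
  u <- X - xbar
  dm2 <- 1 / sum(Z * u^2)
  dc2 <- 1 / sum(Z) + xbar^2 * dm2
  scale <- fit$s_weighted / (fit$n - 2)
  list(dm = sqrt(scale * dm2), dc = sqrt(scale * dc2))
}
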