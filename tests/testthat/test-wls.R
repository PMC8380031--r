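test_that("overall weights merge the two coordinate weights", {
  expect_equal(overall_weight(1, 1, 0), 1)
  expect_equal(overall_weight(4, 1, 2), 0.5)
  # x-errors vanishing reduces to ordinary y-weighting
  expect_equal(overall_weight(1e12, 3, 2), 3, tolerance = 1e-10)
  expect_error(overall_weight(0, 1, 1), "positive")
  expect_error(overall_weight(1, -2, 1), "positive")
})

test_that("the estimating function has its root at the exact slope", {
  d <- regression_dataset(c(-1, 0, 1), c(-1, 0, 1),
                          dx = rep(0.1, 3), dy = rep(0.1, 3))
  expect_equal(cubic_residual(1, d), 0, tolerance = 1e-12)
  d2 <- regression_dataset(c(0.6, 0.7, 0.8, 0.9),
                           y = 3 * c(0.6, 0.7, 0.8, 0.9) - 5,
                           dx = rep(0.02, 4), dy = rep(0.05, 4))
  expect_equal(cubic_residual(3, d2), 0, tolerance = 1e-10)
  # opposite signs on either side of the optimum
  expect_true(sign(cubic_residual(2.5, d2)) != sign(cubic_residual(3.5, d2)))
  expect_error(cubic_residual(1, regression_dataset(1:2, 1:2, 0.1, 0.1)),
               "3 points")
})

test_that("the benchmark fit matches the grid-search minimizer and its roots are genuine", {
  d <- york_benchmark()
  f <- fit_wls(d)
  oracle <- grid_search_wls(d, lo = -5, hi = 5)
  expect_equal(f$m, oracle$m, tolerance = 1e-6)
  expect_equal(f$c, oracle$c, tolerance = 1e-6)
  expect_equal(f$s_weighted, oracle$S, tolerance = 1e-9)
  # the returned slope solves the least-squares cubic
  expect_lt(abs(cubic_residual(f$m, d)), 1e-10 * (1 + abs(f$m)))
  # every adjusted point sits exactly on the fitted line
  expect_lt(max(abs(f$adjusted_points$Y - f$m * f$adjusted_points$X - f$c)),
            1e-12)
  # no slope on a surrounding grid does better than the solution
  S_of <- function(m) {
    wx <- 1 / d$dx^2; wy <- 1 / d$dy^2
    Z <- wx * wy / (m^2 * wy + wx)
    c0 <- (sum(Z * d$y) - m * sum(Z * d$x)) / sum(Z)
    sum(Z * (d$y - m * d$x - c0)^2)
  }
  grid <- seq(f$m / 4, 4 * f$m, length.out = 400)
  expect_true(all(vapply(grid, S_of, 0) >= f$s_weighted - 1e-9))
})

test_that("finite-difference coefficient uncertainties match the analytic form", {
  d <- york_benchmark()
  f <- fit_wls(d)
  an <- analytic_wls_se(d, f)
  expect_equal(f$dm, an$dm, tolerance = 1e-5)
  expect_equal(f$dc, an$dc, tolerance = 1e-5)
  for (seed in c(3, 17, 42)) {
    dr <- random_dataset(seed, n = 10)
    fr <- fit_wls(dr)
    anr <- analytic_wls_se(dr, fr)
    expect_equal(fr$dm, anr$dm, tolerance = 1e-4)
    expect_equal(fr$dc, anr$dc, tolerance = 1e-4)
  }
})

test_that("vanishing x-errors reduce the bivariate fit to OLS", {
  for (seed in 1:10) {
    d <- random_dataset(seed)
    d_eps <- regression_dataset(d$x, d$y, dx = rep(1e-12, nrow(d)),
                                dy = d$dy[1])  # common y uncertainty
    fw <- fit_wls(d_eps, se = FALSE)
    fo <- fit_ols(d)
    expect_equal(fw$m, fo$m, tolerance = 1e-8)
    expect_equal(fw$c, fo$c, tolerance = 1e-8)
  }
})

test_that("swapping the axes inverts the fitted line", {
  for (seed in 1:20) {
    d <- random_dataset(seed, m_range = c(0.3, 5))
    f <- fit_wls(d, se = FALSE)
    fswap <- fit_wls(regression_dataset(d$y, d$x, d$dy, d$dx), se = FALSE)
    expect_equal(fswap$m, 1 / f$m, tolerance = 1e-7)
    expect_equal(fswap$c, -f$c / f$m, tolerance = 1e-7)
  }
})

test_that("rescaling y rescales coefficients and uncertainties alike", {
  for (seed in c(2, 8, 21, 34)) {
    d <- random_dataset(seed)
    f <- fit_wls(d)
    k <- stats::runif(1, 0.2, 4) * sample(c(-1, 1), 1)
    fk <- fit_wls(regression_dataset(d$x, k * d$y, d$dx, abs(k) * d$dy))
    expect_equal(fk$m, k * f$m, tolerance = 1e-7)
    expect_equal(fk$c, k * f$c, tolerance = 1e-7)
    expect_equal(fk$dm, abs(k) * f$dm, tolerance = 1e-4)
    expect_equal(fk$dc, abs(k) * f$dc, tolerance = 1e-4)
  }
})

test_that("equal weights on both axes give orthogonal regression", {
  for (seed in c(5, 13, 29)) {
    d0 <- random_dataset(seed)
    d <- regression_dataset(d0$x, d0$y, dx = 0.07, dy = 0.07)
    f <- fit_wls(d, se = FALSE)
    ma <- major_axis_fit(d$x, d$y)
    expect_equal(f$m, ma$m, tolerance = 1e-8)
    expect_equal(f$c, ma$c, tolerance = 1e-8)
  }
})

test_that("observed- and adjusted-point uncertainties differ little on well-correlated data", {
  st <- simulate_study(simulation_config(seed = 77, lof_ratio = 0,
                                         ndvi_lag = 0, het_sd = 0,
                                         sigma_lwp = 0.04,
                                         sigma_ndvi = 0.01))
  d <- build_regression_dataset(st$groups, pool_treatments = TRUE)
  fa <- fit_wls(d, eval_at = "adjusted")
  fo <- fit_wls(d, eval_at = "observed")
  expect_equal(fa$m, fo$m)                       # same point estimate
  expect_equal(fa$dm, fo$dm, tolerance = 0.1)    # nearby uncertainties
  expect_equal(fa$dc, fo$dc, tolerance = 0.1)
})

test_that("zero uncertainties are floored with a warning instead of failing", {
  d <- regression_dataset(c(0.1, 0.4, 0.7, 0.9),
                          c(-2.5, -2.0, -1.6, -1.2),
                          dx = c(0, 0.02, 0.02, 0.02),
                          dy = c(0.05, 0, 0.05, 0.05))
  expect_warning(expect_warning(f <- fit_wls(d), "NDVI"), "LWP")
  expect_true(is.finite(f$m) && is.finite(f$dm))
})

test_that("underdetermined bivariate fits are rejected", {
  expect_error(fit_wls(regression_dataset(1:2, 1:2, 0.1, 0.1)), "3 points")
})
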