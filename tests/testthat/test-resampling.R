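test_that("the one-sample t test matches its closed form and handles degeneracy", {
  r <- one_sample_ttest(c(1, 2, 3), 2)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r <- one_sample_ttest(c(0.9, 1.1, 1.0, 1.2), 0.77)
  expect_equal(r$t, 4.338, tolerance = 1e-3)
  expect_equal(r$df, 3)
  expect_equal(r$p, 0.0226, tolerance = 1e-2)
  v <- c(0.4, 1.3, 2.2, 0.8)
  expect_equal(one_sample_ttest(v, mean(v))$t, 0, tolerance = 1e-12)
  # zero-variance sample at the reference is degenerate, away from it invalid
  r <- one_sample_ttest(c(2, 2, 2), 2)
  expect_true(r$degenerate)
  expect_equal(c(r$t, r$p), c(0, 1))
  expect_error(one_sample_ttest(c(2, 2, 2), 1), "undefined")
  expect_error(one_sample_ttest(1, 1), "at least 2")
})

resamp_groups <- function(lwp = c(-1.0, -1.2, -1.4, -1.6), n_groups = 6) {
  lapply(seq_len(n_groups), function(i)
    observation_group("cotton", "2018-08-09", "D", 7 + i,
                      lwp_reps = lwp + 0.1 * i,
                      ndvi_reps = 0.6 + 0.02 * i + c(-0.01, 0, 0.01)))
}

test_that("resamples draw with replacement from each group's own replicates", {
  gs <- resamp_groups()
  rs <- draw_resamples(gs, k = 2, n_sets = 20, seed = 3)
  expect_length(rs, 20)
  for (set in rs) for (j in seq_along(set)) {
    g <- set[[j]]
    expect_length(g$lwp_reps, 2)
    expect_true(all(g$lwp_reps %in% gs[[j]]$lwp_reps))
    # resampled means are convex combinations of the originals
    expect_gte(mean(g$lwp_reps), min(gs[[j]]$lwp_reps))
    expect_lte(mean(g$lwp_reps), max(gs[[j]]$lwp_reps))
    # the NDVI side is untouched
    expect_identical(g$ndvi_reps, gs[[j]]$ndvi_reps)
  }
  expect_identical(rs, draw_resamples(gs, k = 2, n_sets = 20, seed = 3))
  expect_false(identical(rs, draw_resamples(gs, 2, 20, seed = 4)))
  expect_error(draw_resamples(gs, k = 1, n_sets = 5, seed = 1), "k >= 2")
  one_rep <- resamp_groups()
  one_rep[[2]]$lwp_reps <- -1.2
  expect_error(draw_resamples(one_rep, 2, 5, 1), "at least 2")
})

test_that("the resampled-mean distribution matches the enumeration oracle", {
  src <- c(-1.0, -1.2, -1.4, -1.6)
  # oracle: all 16 equally likely ordered pairs
  pairs <- expand.grid(src, src)
  oracle_mean <- mean(rowMeans(pairs))
  expect_equal(oracle_mean, -1.3)
  g <- list(observation_group("c", "d", "D", 10, src, 0.7))
  rs <- draw_resamples(g, k = 2, n_sets = 4000, seed = 12)
  means <- vapply(rs, function(s) mean(s[[1]]$lwp_reps), 0)
  se <- sqrt(stats::var(rowMeans(pairs)) / 4000)
  expect_lt(abs(mean(means) - oracle_mean), 4 * se)
})

test_that("constant replicates resample to themselves with zero SEM", {
  g <- list(observation_group("c", "d", "D", 10, rep(-1.2, 4), 0.7))
  rs <- draw_resamples(g, k = 3, n_sets = 5, seed = 2)
  for (set in rs) {
    expect_equal(set[[1]]$lwp_reps, rep(-1.2, 3))
    expect_equal(summarize_group(set[[1]]$lwp_reps)$sem, 0)
  }
})

test_that("refitting a noise-free study returns the truth for every set", {
  cfg <- simulation_config(sigma_lwp = 0, sigma_ndvi = 0, ndvi_lag = 0,
                           seed = 8)
  st <- simulate_study(cfg)
  rs <- draw_resamples(st$groups, k = 3, n_sets = 6, seed = 5)
  co <- suppressMessages(refit_resamples(rs, method = "OLS"))
  expect_equal(nrow(co), 6)
  expect_equal(co$m, rep(cfg$m_true, 6), tolerance = 1e-9)
  expect_equal(co$c, rep(cfg$c_true, 6), tolerance = 1e-9)
  cw <- suppressWarnings(suppressMessages(refit_resamples(rs, method = "WLS")))
  expect_equal(cw$m, rep(cfg$m_true, 6), tolerance = 1e-8)
})

test_that("the full resampling study reports references, coefficients and t tests", {
  st <- simulate_study(simulation_config(seed = 21))
  rs <- suppressWarnings(
    resample_study(st$groups, k = 2, n_sets = 10, seed = 4))
  expect_s3_class(rs, "resample_study")
  expect_named(rs$methods, c("WLS", "OLS"))
  for (pm in rs$methods) {
    expect_equal(nrow(pm$coefficients), 10)
    expect_s3_class(pm$reference, "fit_result")
    expect_named(pm$t_tests, c("m", "c", "dm", "dc"))
    expect_true(pm$t_tests$m$p > 0 && pm$t_tests$m$p <= 1)
  }
})

test_that("shrinking LWP replication inflates WLS uncertainty more than OLS", {
  # expectation-level version of the replicate-count experiment: averaged
  # over repetitions, the mean resampled dm is ordered
  # dm(k = 2) >= dm(k = 3) >= dm(full), and the bivariate fit (whose
  # weights feel the SEMs) responds more strongly than OLS
  nrep <- 12
  ratio_w <- ratio_o <- matrix(NA_real_, nrep, 2)
  for (r in seq_len(nrep)) {
    st <- simulate_study(simulation_config(seed = 4000 + r))
    full <- build_regression_dataset(st$groups, pool_treatments = TRUE)
    fw <- suppressWarnings(fit_wls(full))
    fo <- fit_ols(full)
    for (ki in 1:2) {
      k <- c(2, 3)[ki]
      rs <- draw_resamples(st$groups, k, n_sets = 20, seed = 600 + r)
      cw <- suppressWarnings(suppressMessages(refit_resamples(rs, "WLS")))
      co <- suppressMessages(refit_resamples(rs, "OLS"))
      ratio_w[r, ki] <- mean(cw$dm, na.rm = TRUE) / fw$dm
      ratio_o[r, ki] <- mean(co$dm, na.rm = TRUE) / fo$dm
    }
  }
  expect_gt(mean(ratio_w[, 1]), mean(ratio_w[, 2]))  # k = 2 worse than k = 3
  expect_gt(mean(ratio_w[, 2]), 1)                   # both worse than full
  expect_gt(mean(ratio_w[, 1]), mean(ratio_o[, 1]))  # WLS feels it more
  expect_gt(mean(ratio_w[, 2]), mean(ratio_o[, 2]))
})
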