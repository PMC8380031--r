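#' Draw with-replacement resamples of the LWP replicates
#'
#' For each of `n_sets` resample sets, every group's LWP replicates are
#' replaced by `k` draws with replacement from its original readings; the
#' NDVI side is left untouched. This emulates having measured only `k`
#' leaves per group, and quantifies what the reduced replication does to
#' the group SEMs and, downstream, the fitted-coefficient uncertainties.
#' Set `j` uses substream `j` of `seed`, so individual sets are
#' reproducible in isolation.
#'
#' @param groups List of [observation_group()]s, each with >= 2 LWP
#'   replicates.
#' @param k Replicates drawn per group (>= 2; typically 2 or 3).
#' @param n_sets Number of resample sets (default 20).
#' @param seed Integer seed.
#' @return List of `n_sets` group lists.
#' @export
draw_resamples <- function(groups, k, n_sets = 20L, seed = 1L) {
  stopifnot(k >= 2)
  if (any(vapply(groups, function(g) length(g$lwp_reps), 0L) < 2))
    stop("every group needs at least 2 original LWP replicates")
  lapply(seq_len(n_sets), function(j) {
    set.seed((seed + 7919L * j) %% .Machine$integer.max)
    lapply(groups, function(g) {
      g$lwp_reps <- sample(g$lwp_reps, k, replace = TRUE)
      g
    })
  })
}

#' Refit each resample set by the chosen method
#'
#' Every resampled group table is re-aggregated (group means/SEMs via
#' [summarize_group()] inside [build_regression_dataset()]) and refit. A
#' set whose resampled LWP SEMs are all zero still fits through the
#' zero-uncertainty floor of the bivariate solver; a set failing the fit
#' preconditions outright is recorded as `NA` and excluded from the t
#' tests, with a message giving the failure count.
#'
#' @param resamples Output of [draw_resamples()].
#' @param method `"OLS"` or `"WLS"`.
#' @param pool_treatments Passed to [build_regression_dataset()].
#' @return A data.frame with one row per set: `m`, `c`, `dm`, `dc`.
#' @export
refit_resamples <- function(resamples, method = c("WLS", "OLS"),
                            pool_treatments = TRUE) {
  method <- match.arg(method)
  rows <- lapply(resamples, function(gs) {
    tryCatch({
      d <- build_regression_dataset(gs, pool_treatments = pool_treatments)
      f <- suppressWarnings(
        if (method == "OLS") fit_ols(d) else fit_wls(d))
      data.frame(m = f$m, c = f$c, dm = f$dm, dc = f$dc)
    }, error = function(e)
      data.frame(m = NA_real_, c = NA_real_, dm = NA_real_, dc = NA_real_))
  })
  out <- do.call(rbind, rows)
  nf <- sum(is.na(out$m))
  if (nf > 0) message(nf, " resample set(s) failed to fit and were excluded")
  out
}

#' One-sample t test against a reference value
#'
#' Thin wrapper over [stats::t.test()] returning `(t, df, p)`, plus
#' explicit handling of the degenerate zero-variance sample: when all
#' values equal the reference, `t = 0`, `p = 1` and `degenerate = TRUE`;
#' a zero-variance sample away from the reference is rejected (the
#' statistic is unbounded).
#'
#' @param values Numeric sample, length >= 2.
#' @param mu0 Reference value.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
one_sample_ttest <- function(values, mu0) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0) {
    if (isTRUE(all.equal(mean(values), mu0)))
      return(list(t = 0, df = n - 1, p = 1, degenerate = TRUE))
    stop("zero sample variance with mean != mu0: t statistic undefined")
  }
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Replicate-count resampling study of coefficient uncertainty
#'
#' The full experiment: fit the reference calibration from the complete
#' replicate set, then for `k` LWP replicates drawn with replacement
#' (`n_sets` times) refit by each requested method and compare the per-set
#' coefficients and uncertainties (`m`, `c`, `dm`, `dc`) against the
#' reference values with one-sample t tests. The signature finding this
#' reproduces: shrinking the LWP replication inflates `dm`/`dc` under the
#' errors-in-both-coordinates fit (whose weights feel the SEMs) but not
#' under OLS (which ignores them).
#'
#' @param groups List of [observation_group()]s.
#' @param k Replicates drawn per group.
#' @param n_sets Resample sets (default 20).
#' @param methods Character subset of `c("WLS", "OLS")`.
#' @param seed Integer seed.
#' @param pool_treatments Passed to the dataset builder.
#' @return A `resample_study`: per-method list with `reference` fit,
#'   per-set `coefficients` data.frame, summary means, and `t_tests`
#'   (per quantity: t, df, p), plus `k`, `n_sets`, `seed`.
#' @export
resample_study <- function(groups, k, n_sets = 20L,
                           methods = c("WLS", "OLS"), seed = 1L,
                           pool_treatments = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  resamples <- draw_resamples(groups, k, n_sets, seed)
  full <- build_regression_dataset(groups, pool_treatments = pool_treatments)
  per_method <- lapply(methods, function(meth) {
    ref <- suppressWarnings(
      if (meth == "OLS") fit_ols(full) else fit_wls(full))
    coefs <- refit_resamples(resamples, method = meth,
                             pool_treatments = pool_treatments)
    ok <- !is.na(coefs$m)
    tt <- lapply(c(m = "m", c = "c", dm = "dm", dc = "dc"), function(q) {
      vals <- coefs[[q]][ok]
      if (length(vals) < 2) return(NULL)
      tryCatch(one_sample_ttest(vals, ref[[q]]), error = function(e) NULL)
    })
    list(method = meth, reference = ref, coefficients = coefs,
         means = colMeans(coefs[ok, , drop = FALSE]), t_tests = tt)
  })
  names(per_method) <- methods
  structure(list(methods = per_method, k = k, n_sets = n_sets, seed = seed),
            class = "resample_study")
}

#' @export
print.resample_study <- function(x, digits = 3, ...) {
  cat(sprintf("Resampling study: k = %d LWP replicates, %d sets, seed %d\n",
              x$k, x$n_sets, x$seed))
  for (pm in x$methods) {
    cat(sprintf("  %s: reference dm = %s, mean resampled dm = %s (p = %s)\n",
                pm$method,
                format(pm$reference$dm, digits = digits),
                format(pm$means[["dm"]], digits = digits),
                if (!is.null(pm$t_tests$dm))
                  format(pm$t_tests$dm$p, digits = digits) else "NA"))
  }
  invisible(x)
}
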