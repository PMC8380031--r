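#' Configuration of a synthetic field campaign
#'
#' Defines the ground truth and sampling design of a simulated diurnal
#' NDVI/LWP survey: a linear relation `LWP = m_true * NDVI + c_true`, a
#' unimodal midday depression of LWP over the daylight window, per-treatment
#' effects, and iid Gaussian replicate noise on both the pressure-chamber
#' LWP readings and the per-plot NDVI scans. Group SEMs then arise
#' naturally as `sd/sqrt(n)` during aggregation.
#'
#' Treatments can differ in two ways. An entry of `treatment_lwp_shift`
#' moves a treatment's whole diurnal LWP course along the shared
#' calibration line (deficit irrigation running systematically more
#' stressed), so pooled treatments still satisfy the relation exactly. An
#' entry of `treatments` adds an NDVI offset *off* the line, giving
#' treatments a shared slope but different intercepts; nonzero offsets make
#' pooling a misspecification, which is exactly what they are for
#' (stress-testing the pooling decision). The defaults emulate a cotton
#' campaign where deficit and full irrigation showed no coefficient
#' difference: slope 4.24 MPa per NDVI unit, intercept -5.19 MPa, nine
#' hourly scans 08:00-16:00 local, treatments "D" (0.2 MPa more stressed,
#' on-line) and "F", zero off-line offsets, 4 LWP leaves and 3 NDVI plot
#' replicates per group, and noise scales placing the group SEMs at a few
#' percent of the measurement ranges (the 4-20 percent band typical of
#' such campaigns).
#'
#' @param m_true True slope, MPa per NDVI unit (nonzero).
#' @param c_true True intercept, MPa.
#' @param hours Local clock hours scanned.
#' @param treatments Named numeric vector of additive off-line NDVI offsets
#'   per treatment label (zero keeps a treatment on the calibration line).
#' @param treatment_lwp_shift Named numeric vector (same names) of additive
#'   LWP shifts in MPa applied along the line.
#' @param lwp_base Pre-dawn (unstressed) LWP, MPa.
#' @param lwp_depth Amplitude of the midday depression, MPa (>= 0).
#' @param n_lwp_reps Pressure-chamber leaves per group (>= 2).
#' @param n_ndvi_reps NDVI plot replicates per group (>= 1).
#' @param sigma_lwp Per-leaf LWP noise sd, MPa.
#' @param sigma_ndvi Per-plot NDVI noise sd.
#' @param het_sd Log-scale sd of the latent per-group noise factor
#'   `lambda_g ~ lognormal(-het_sd^2/2, het_sd)` (mean 1), which scales the
#'   LWP replicate noise: groups measured under unfavourable conditions
#'   (wind, changing light, heat) have more scattered replicates.
#' @param ndvi_lag Hysteresis lag in hours: the canopy NDVI of a group
#'   tracks the leaf water status `ndvi_lag` hours earlier rather than the
#'   instantaneous LWP, so the diurnal trajectory traces a loop around the
#'   calibration line (points below the line while LWP falls in the
#'   morning, above it during afternoon recovery). This is the dominant
#'   lack-of-fit of real campaigns: it inflates the residual scatter far
#'   beyond the measurement SEMs and does not shrink with more replicates,
#'   yet - being symmetric between the two arms of the loop - biases the
#'   fitted slope far less than unstructured scatter of the same size.
#'   Zero disables the loop.
#' @param lof_ratio Irregular lack-of-fit: each group's true LWP is
#'   additionally displaced off the line by an iid mean-zero draw with sd
#'   `lof_ratio * sigma_lwp / sqrt(n_lwp_reps)`. Where the hysteresis loop
#'   captures the systematic within-day structure, this term captures the
#'   campaign-to-campaign irregularities (weather, canopy state, sensor
#'   drift) that change between days; unlike replicate noise it does not
#'   shrink with more leaves. Zero puts every group's truth exactly on the
#'   loop (and, with `ndvi_lag = 0`, exactly on the line).
#' @param dawn,dusk Daylight window (local hours); solar noon is the
#'   midpoint.
#' @param crop,date Labels carried through to the generated tables.
#' @param seed Integer seed; the same config and seed regenerate the study
#'   bit-identically.
#' @return A `simulation_config` list.
#' @seealso [simulate_study()], [simulate_diurnal_lwp()]
#' @export
simulation_config <- function(m_true = 4.24, c_true = -5.19,
                              hours = 8:16,
                              treatments = c(D = 0, F = 0),
                              treatment_lwp_shift = c(D = -0.2, F = 0),
                              lwp_base = -1.6, lwp_depth = 1.0,
                              n_lwp_reps = 4L, n_ndvi_reps = 3L,
                              sigma_lwp = 0.11, sigma_ndvi = 0.028,
                              het_sd = 0.5, ndvi_lag = 1, lof_ratio = 2.5,
                              dawn = 6, dusk = 20,
                              crop = "cotton", date = "2018-08-09",
                              seed = 1L) {
  if (m_true == 0) stop("m_true = 0: the LWP-NDVI relation is not invertible")
  if (n_lwp_reps < 2) stop("n_lwp_reps must be >= 2 (SEM needs replication)")
  if (n_ndvi_reps < 1) stop("n_ndvi_reps must be >= 1")
  if (sigma_lwp < 0 || sigma_ndvi < 0 || het_sd < 0 || ndvi_lag < 0 ||
      lof_ratio < 0)
    stop("noise parameters must be >= 0")
  if (lwp_depth < 0) stop("lwp_depth must be >= 0")
  if (dusk <= dawn) stop("dusk must be after dawn")
  if (any(hours < dawn | hours > dusk))
    stop("all scan hours must lie inside the daylight window")
  if (any(hours - ndvi_lag < dawn))
    stop("ndvi_lag reaches before dawn for the earliest scan hour")
  if (is.null(names(treatments)) || anyNA(names(treatments)))
    stop("`treatments` must be a named vector of NDVI offsets")
  if (!setequal(names(treatment_lwp_shift), names(treatments))) {
    if (!missing(treatment_lwp_shift))
      stop("`treatment_lwp_shift` names must match `treatments`")
    treatment_lwp_shift <- stats::setNames(numeric(length(treatments)),
                                           names(treatments))
  }
  cfg <- list(m_true = m_true, c_true = c_true, hours = hours,
              treatments = treatments,
              treatment_lwp_shift = treatment_lwp_shift,
              lwp_base = lwp_base,
              lwp_depth = lwp_depth, n_lwp_reps = as.integer(n_lwp_reps),
              n_ndvi_reps = as.integer(n_ndvi_reps),
              sigma_lwp = sigma_lwp, sigma_ndvi = sigma_ndvi,
              het_sd = het_sd, ndvi_lag = ndvi_lag, lof_ratio = lof_ratio,
              dawn = dawn, dusk = dusk, crop = crop, date = date,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  # the noise-free NDVI must stay inside the physical range (the lagged
  # water status is what the canopy reflects)
  lwp <- simulate_diurnal_lwp(cfg, hours - ndvi_lag)
  for (tr in names(treatments)) {
    ndvi <- (lwp + treatment_lwp_shift[[tr]] - c_true) / m_true +
      treatments[[tr]]
    if (any(ndvi <= -1 | ndvi >= 1))
      stop("config implies true NDVI outside (-1, 1); adjust m_true/c_true/",
           "lwp_base/lwp_depth or the treatment effects")
  }
  cfg
}

#' Diurnal course of the true group-level leaf water potential
#'
#' A deterministic unimodal midday depression: LWP equals `lwp_base` at
#' dawn and dusk and dips to `lwp_base - lwp_depth` at solar noon (the
#' midpoint of the daylight window), following a sine-squared bump
#' `s(h) = sin^2(pi * (h - dawn) / (dusk - dawn))`, so that e.g. halfway
#' between dawn and noon `s = 1/2`.
#'
#' @param config A [simulation_config()].
#' @param hour Local clock hour(s), inside `[dawn, dusk]`.
#' @return True LWP in MPa, one value per hour.
#' @export
simulate_diurnal_lwp <- function(config, hour) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(hour < config$dawn | hour > config$dusk))
    stop("hour outside the daylight window [", config$dawn, ", ",
         config$dusk, "]")
  s <- sin(pi * (hour - config$dawn) / (config$dusk - config$dawn))^2
  config$lwp_base - config$lwp_depth * s
}

#' Simulate one field study with known ground truth
#'
#' For every (hour, treatment) cell: the true group LWP is the diurnal
#' course from [simulate_diurnal_lwp()] plus the treatment's along-line
#' LWP shift; the true group NDVI inverts the linear relation at the
#' *lagged* water status, `(LWP(hour - ndvi_lag) + shift - c_true)/m_true`,
#' plus the treatment's off-line offset - the hysteresis loop that real
#' canopies trace around the calibration line; a latent noise factor
#' `lambda_g` is drawn per group; replicate LWP values add iid Gaussian
#' noise with sd `lambda_g * sigma_lwp`, NDVI replicates with sd
#' `sigma_ndvi`. Each
#' group draws from its own substream, derived deterministically from the
#' global seed, so the output is independent of generation order and
#' bit-reproducible.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_study`: list with `groups` (list of
#'   [observation_group()]), `truth` (`m_true`, `c_true`, and a per-group
#'   table of true LWP/NDVI, the latent noise factor and the true
#'   uncertainty scales), and the `config`.
#' @examples
#' study <- simulate_study(simulation_config(seed = 42))
#' length(study$groups)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cells <- expand.grid(hour = config$hours,
                       treatment = names(config$treatments),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$treatment, cells$hour), , drop = FALSE]
  groups <- vector("list", nrow(cells))
  truth_tab <- cells
  truth_tab$lwp_true <- NA_real_
  truth_tab$ndvi_true <- NA_real_
  truth_tab$lambda <- NA_real_
  truth_tab$lwp_sem_true <- NA_real_
  truth_tab$ndvi_sem_true <- NA_real_
  for (i in seq_len(nrow(cells))) {
    hr <- cells$hour[i]; tr <- cells$treatment[i]
    lwp_true <- simulate_diurnal_lwp(config, hr) +
      config$treatment_lwp_shift[[tr]]
    lwp_lagged <- simulate_diurnal_lwp(config, hr - config$ndvi_lag) +
      config$treatment_lwp_shift[[tr]]
    ndvi_true <- (lwp_lagged - config$c_true) / config$m_true +
      config$treatments[[tr]]
    set.seed((config$seed + 7919L * i) %% .Machine$integer.max)
    lambda_g <- stats::rlnorm(1, -config$het_sd^2 / 2, config$het_sd)
    lwp_true <- lwp_true + stats::rnorm(
      1, 0, config$lof_ratio * config$sigma_lwp / sqrt(config$n_lwp_reps))
    lwp_reps <- lwp_true +
      stats::rnorm(config$n_lwp_reps, 0, lambda_g * config$sigma_lwp)
    ndvi_reps <- ndvi_true + stats::rnorm(config$n_ndvi_reps, 0, config$sigma_ndvi)
    groups[[i]] <- observation_group(
      crop = config$crop, date = config$date, treatment = tr,
      hour_local = hr, lwp_reps = lwp_reps, ndvi_reps = ndvi_reps,
      check_sign = FALSE)
    truth_tab$lwp_true[i] <- lwp_true
    truth_tab$ndvi_true[i] <- ndvi_true
    truth_tab$lambda[i] <- lambda_g
    truth_tab$lwp_sem_true[i] <- lambda_g * config$sigma_lwp /
      sqrt(config$n_lwp_reps)
    truth_tab$ndvi_sem_true[i] <- config$sigma_ndvi /
      sqrt(config$n_ndvi_reps)
  }
  structure(list(groups = groups,
                 truth = list(m_true = config$m_true, c_true = config$c_true,
                              groups = truth_tab),
                 config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "Simulated study: %d groups (%d hours x %d treatments), truth m = %g, c = %g, seed = %d\n",
    length(x$groups), length(x$config$hours), length(x$config$treatments),
    x$truth$m_true, x$truth$c_true, x$config$seed))
  invisible(x)
}

#' Write a simulated study in the raw-campaign CSV layouts
#'
#' Emits the same files the ingest module reads: an LWP replicate table
#' (`lwp_replicates.csv`: crop, date, treatment, hour, rep, lwp_mpa), a
#' reflectance scan log (`scan_log.csv`: timestamp_utc, lat, lon, rho670,
#' rho730, rho780, plot) whose per-record NDVI reproduces the simulated
#' replicate values (band reflectances are back-solved from NDVI at a fixed
#' band sum of 0.5, with GPS positions stepped so the records register as
#' moving), and a ground-truth sidecar `truth.json` holding `m_true`,
#' `c_true` and the seed.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lwp <- do.call(rbind, lapply(study$groups, function(g) {
    data.frame(crop = g$crop, date = g$date, treatment = g$treatment,
               hour = g$hour_local, rep = seq_along(g$lwp_reps),
               lwp_mpa = g$lwp_reps)
  }))
  utils::write.csv(lwp, file.path(dir, "lwp_replicates.csv"), row.names = FALSE)

  scan <- do.call(rbind, lapply(seq_along(study$groups), function(i) {
    g <- study$groups[[i]]
    ndvi <- g$ndvi_reps
    band_sum <- 0.5
    rho780 <- band_sum * (1 + ndvi) / 2
    rho670 <- band_sum * (1 - ndvi) / 2
    ts_local <- as.POSIXct(paste0(g$date, " 00:00:00"), tz = "UTC") +
      g$hour_local * 3600 + seq_along(ndvi) * 30
    data.frame(
      timestamp_utc = format(ts_local + 5 * 3600, "%Y-%m-%d %H:%M:%S"),
      lat = 29.2 + i * 1e-4 + seq_along(ndvi) * 2e-5,
      lon = -99.7 + seq_along(ndvi) * 2e-5,
      rho670 = rho670, rho730 = (rho670 + rho780) / 2, rho780 = rho780,
      plot = paste0(g$treatment, seq_along(ndvi)))
  }))
  scan <- scan[order(scan$timestamp_utc), , drop = FALSE]
  utils::write.csv(scan, file.path(dir, "scan_log.csv"), row.names = FALSE)

  truth <- list(m_true = study$truth$m_true, c_true = study$truth$c_true,
                seed = study$config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
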