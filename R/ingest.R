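#' One observation group of the field campaign
#'
#' A (crop, date, treatment, hour) cell holding the pressure-chamber LWP
#' replicates (2-6 leaves) and NDVI plot replicates before aggregation.
#' LWP is conventionally non-positive (a tension); positive values trigger
#' a warning, not an error, because sign-flipped balancing-pressure entries
#' are a common data-entry slip worth surfacing.
#'
#' @param crop,date,treatment Character labels; treatment is typically
#'   `"D"` (deficit) or `"F"` (full irrigation).
#' @param hour_local Local clock hour of the measurement.
#' @param lwp_reps Numeric LWP replicates, MPa (length >= 2 for a SEM).
#' @param ndvi_reps Numeric NDVI replicates (length >= 1).
#' @param check_sign Warn on positive LWP values (default `TRUE`).
#' @return An `observation_group` list.
#' @export
observation_group <- function(crop, date, treatment, hour_local,
                              lwp_reps, ndvi_reps, check_sign = TRUE) {
  if (length(lwp_reps) < 1 || length(ndvi_reps) < 1)
    stop("a group needs at least one LWP and one NDVI replicate")
  if (check_sign && any(lwp_reps > 0))
    warning("positive LWP value(s) in group ", crop, "/", date, "/",
            treatment, "/", hour_local,
            " - water potentials are conventionally <= 0 MPa")
  structure(list(crop = crop, date = date, treatment = treatment,
                 hour_local = hour_local,
                 lwp_reps = as.numeric(lwp_reps),
                 ndvi_reps = as.numeric(ndvi_reps)),
            class = "observation_group")
}

#' Normalized difference vegetation index from band reflectances
#'
#' `NDVI = (rho780 - rho670) / (rho780 + rho670)`, the normalized contrast
#' between near-infrared (780 nm) and red (670 nm) canopy reflectance.
#' Vectorised.
#'
#' @param rho670,rho780 Reflectance fractions, both >= 0 with a positive sum.
#' @return NDVI values in (-1, 1].
#' @examples
#' compute_ndvi(0.1, 0.5)  # 0.6667
#' @export
compute_ndvi <- function(rho670, rho780) {
  if (any(rho670 < 0) || any(rho780 < 0))
    stop("reflectances must be non-negative")
  s <- rho670 + rho780
  if (any(s <= 0))
    stop("rho670 + rho780 must be positive to form NDVI")
  (rho780 - rho670) / s
}

#' Convert datalogger UTC timestamps to local (Central Standard) time
#'
#' The sensor logs in UTC; local time during the campaign follows the
#' fixed offset CST = UTC - 5 hours (the daylight-savings semantics are
#' baked into the constant). Date rollover is handled by POSIX arithmetic.
#'
#' @param t A `POSIXct` timestamp (or vector) in UTC, or a string parsed as
#'   UTC `"%Y-%m-%d %H:%M:%S"`.
#' @param offset_hours Hours subtracted from UTC; default 5.
#' @return `POSIXct` local times (tz kept as UTC-labelled clock time).
#' @export
utc_to_local <- function(t, offset_hours = 5) {
  if (is.character(t))
    t <- as.POSIXct(t, tz = "UTC")
  t - offset_hours * 3600
}

#' Read a raw reflectance scan log
#'
#' Expects columns `timestamp_utc`, `lat`, `lon`, `rho670`, `rho730`,
#' `rho780` and optionally `plot` and `moving_flag`. Timestamps must be
#' monotone non-decreasing; the NDVI of each record is computed and
#' attached.
#'
#' @param path CSV file path.
#' @return A data.frame of scan records with parsed `timestamp_utc`
#'   (POSIXct UTC), local time `timestamp_local`, and `ndvi`.
#' @export
read_scan_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_utc", "lat", "lon", "rho670", "rho730", "rho780")
  if (!all(need %in% names(df)))
    stop("scan log must have columns: ", paste(need, collapse = ", "))
  df$timestamp_utc <- as.POSIXct(df$timestamp_utc, tz = "UTC")
  if (is.unsorted(df$timestamp_utc))
    stop("scan log timestamps must be monotone non-decreasing")
  df$timestamp_local <- utc_to_local(df$timestamp_utc)
  df$ndvi <- compute_ndvi(df$rho670, df$rho780)
  df
}

#' Read an LWP replicate table
#'
#' Expects columns `crop`, `date`, `treatment`, `hour`, `rep`, `lwp_mpa`:
#' one row per pressure-chamber reading.
#'
#' @param path CSV file path.
#' @return The data.frame of replicate readings.
#' @export
read_lwp_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("crop", "date", "treatment", "hour", "rep", "lwp_mpa")
  if (!all(need %in% names(df)))
    stop("LWP table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Filtering policy for raw scan logs
#'
#' @param movement_threshold Minimum GPS displacement (metres) over the
#'   trailing window for a record to count as moving; records below it are
#'   idle (sensor parked between scan rounds). Default 0.5 m.
#' @param movement_window Trailing window length in seconds (default 10).
#' @param warmup_windows List of length-2 `POSIXct` (UTC) vectors
#'   `c(start, end)`; records inside any window are dropped (sensor not yet
#'   warmed up). `NULL` disables.
#' @param time_window Optional length-2 `POSIXct` (UTC) keep-window.
#' @param geofence Optional named list `list(lat = c(min, max),
#'   lon = c(min, max))`; records outside the box are dropped.
#' @param apply_movement Apply the idle filter at all? Default `TRUE`.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(movement_threshold = 0.5, movement_window = 10,
                          warmup_windows = NULL, time_window = NULL,
                          geofence = NULL, apply_movement = TRUE) {
  structure(list(movement_threshold = movement_threshold,
                 movement_window = movement_window,
                 warmup_windows = warmup_windows,
                 time_window = time_window,
                 geofence = geofence,
                 apply_movement = apply_movement),
            class = "filter_policy")
}

#' Filter idle, warm-up and out-of-bounds records from a scan log
#'
#' Applies, in order: the idle filter (GPS displacement between each record
#' and the earliest record inside its trailing time window below the
#' movement threshold), warm-up exclusion windows, the keep time-window,
#' and the geofence. Survivors keep their order and carry a
#' `moving_flag = TRUE` column; if the input already has a `moving_flag`
#' column it is reused instead of being recomputed, which makes the filter
#' idempotent (re-filtering survivors, whose idle neighbours are gone,
#' would otherwise reclassify them). Record counts before/after each stage
#' are reported via `message()`.
#'
#' @param records Scan-record data.frame from [read_scan_log()] (time
#'   sorted).
#' @param policy A [filter_policy()].
#' @return The surviving records, in order; zero rows (with a warning) if
#'   everything is filtered.
#' @export
filter_scan_records <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(records) == 0) return(records)
  keep <- rep(TRUE, nrow(records))

  if (policy$apply_movement) {
    if (is.null(records$moving_flag)) {
      records$moving_flag <- .moving_flags(records, policy$movement_threshold,
                                           policy$movement_window)
    }
    keep <- keep & records$moving_flag
    message(sum(keep), "/", nrow(records), " records after idle filter")
  }
  if (!is.null(policy$warmup_windows)) {
    for (w in policy$warmup_windows)
      keep <- keep & !(records$timestamp_utc >= w[1] &
                         records$timestamp_utc <= w[2])
    message(sum(keep), "/", nrow(records), " records after warm-up exclusion")
  }
  if (!is.null(policy$time_window)) {
    keep <- keep & records$timestamp_utc >= policy$time_window[1] &
      records$timestamp_utc <= policy$time_window[2]
    message(sum(keep), "/", nrow(records), " records after time window")
  }
  if (!is.null(policy$geofence)) {
    gf <- policy$geofence
    keep <- keep & records$lat >= gf$lat[1] & records$lat <= gf$lat[2] &
      records$lon >= gf$lon[1] & records$lon <= gf$lon[2]
    message(sum(keep), "/", nrow(records), " records after geofence")
  }
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0)
    warning("all scan records were filtered out")
  out
}

# displacement (m) between each record and the earliest record within its
# trailing window; a lone record in its window has zero displacement (idle)
.moving_flags <- function(records, threshold, window) {
  t <- as.numeric(records$timestamp_utc)
  n <- length(t)
  disp <- numeric(n)
  j <- 1L
  for (i in seq_len(n)) {
    while (t[j] < t[i] - window) j <- j + 1L
    disp[i] <- geosphere::distHaversine(
      c(records$lon[j], records$lat[j]),
      c(records$lon[i], records$lat[i]))
  }
  disp >= threshold
}

#' Mean and standard error of a replicate sample
#'
#' SEM is the sample standard deviation (n - 1 denominator) divided by
#' `sqrt(n)`. With a single value the mean is returned and the SEM is `NA`
#' (flagged missing).
#'
#' @param values Numeric vector, length >= 1.
#' @return List with `mean`, `sem` and `n`.
#' @examples
#' summarize_group(c(-1.0, -1.2, -1.4, -1.6))  # mean -1.3, sem 0.1291
#' @export
summarize_group <- function(values) {
  n <- length(values)
  if (n < 1) stop("empty sample")
  list(mean = mean(values),
       sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Assemble the paired regression dataset from observation groups
#'
#' One point per group: x is the NDVI replicate mean, y the LWP replicate
#' mean, dx and dy the respective SEMs, ordered deterministically by
#' (date, treatment, hour). Groups from multiple treatments are only
#' combined when `pool_treatments = TRUE` (appropriate once a same-slope
#' check, or an explicit user decision, justifies pooling); otherwise the
#' presence of more than one treatment is an error so pooling can never
#' happen by accident.
#'
#' Groups with a single NDVI replicate (unreplicated scans) yield `dx = NA`
#' and flag the dataset OLS-only; the bivariate fitter then requires the
#' user to supply an NDVI uncertainty explicitly.
#'
#' @param groups List of [observation_group()]s.
#' @param pool_treatments Allow groups from different treatments in one
#'   dataset (default `FALSE`).
#' @param label Dataset label; by default derived from crop/date/treatments.
#' @return A [regression_dataset()].
#' @export
build_regression_dataset <- function(groups, pool_treatments = FALSE,
                                     label = NULL) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, TRUE, "observation_group")))
  trs <- vapply(groups, `[[`, "", "treatment")
  if (length(unique(trs)) > 1 && !pool_treatments)
    stop("groups span treatments ", paste(unique(trs), collapse = ", "),
         "; set pool_treatments = TRUE to combine them deliberately")
  ord <- order(vapply(groups, `[[`, "", "date"), trs,
               vapply(groups, `[[`, 0, "hour_local"))
  groups <- groups[ord]
  lwp <- lapply(groups, function(g) summarize_group(g$lwp_reps))
  ndvi <- lapply(groups, function(g) summarize_group(g$ndvi_reps))
  if (is.null(label)) {
    g1 <- groups[[1]]
    label <- paste(g1$crop, g1$date,
                   paste(sort(unique(trs)), collapse = "/"), sep = " ")
  }
  regression_dataset(
    x = vapply(ndvi, `[[`, 0, "mean"),
    y = vapply(lwp, `[[`, 0, "mean"),
    dx = vapply(ndvi, `[[`, 0, "sem"),
    dy = vapply(lwp, `[[`, 0, "sem"),
    label = label)
}

#' Pair a filtered scan log with an LWP replicate table into groups
#'
#' Records are assigned to (treatment, local hour) cells: the treatment is
#' the leading letters of the `plot` label, the hour is the local clock
#' hour of the record. NDVI replicates within a cell are the per-plot mean
#' NDVI values (one replicate per distinct plot). Cells are matched to the
#' LWP table on (crop, date, treatment, hour); cells missing from either
#' side are dropped with a message.
#'
#' @param scans Filtered scan-record data.frame (with `ndvi`,
#'   `timestamp_local`, `plot`).
#' @param lwp_table LWP replicate data.frame from [read_lwp_table()].
#' @return List of [observation_group()]s.
#' @export
scans_to_groups <- function(scans, lwp_table) {
  if (is.null(scans$plot))
    stop("scan records need a `plot` column to infer treatments")
  scans$treatment <- sub("[0-9]+$", "", scans$plot)
  scans$hour <- as.integer(format(scans$timestamp_local, "%H"))
  scans$date <- format(scans$timestamp_local, "%Y-%m-%d")
  groups <- list()
  for (key in unique(paste(lwp_table$crop, lwp_table$date,
                           lwp_table$treatment, lwp_table$hour))) {
    parts <- strsplit(key, " ")[[1]]
    lsub <- lwp_table[lwp_table$crop == parts[1] & lwp_table$date == parts[2] &
                        lwp_table$treatment == parts[3] &
                        lwp_table$hour == as.numeric(parts[4]), ]
    ssub <- scans[scans$date == parts[2] & scans$treatment == parts[3] &
                    scans$hour == as.numeric(parts[4]), ]
    if (nrow(ssub) == 0) {
      message("no scans for cell ", key, "; skipped")
      next
    }
    ndvi_reps <- tapply(ssub$ndvi, ssub$plot, mean)
    groups[[length(groups) + 1]] <- observation_group(
      crop = parts[1], date = parts[2], treatment = parts[3],
      hour_local = as.numeric(parts[4]),
      lwp_reps = lsub$lwp_mpa, ndvi_reps = as.numeric(ndvi_reps))
  }
  groups
}
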