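# Ground-truth concentration model and hourly simulation. The generative
# assumption mirrors what a log-linear land-use regression presumes: hourly
# log concentration at a station is a base level plus a linear combination
# of predictor values at that station, with per-season multipliers, a
# city-wide shared hourly component (common meteorology), and independent
# hourly noise. NOx is NO + NO2 by construction at every hour.

#' Ground truth for the synthetic concentration surface
#'
#' @param active named numeric vector of true log-scale coefficients, named
#'   by predictor (e.g. `c("DIST.TACZ" = -2.5e-4, "GRS.300" = -4e-6)`).
#'   Coefficient signs must respect the catalog's a-priori effect direction
#'   for that predictor class (where one is assigned).
#' @param seasonal_shift list with elements `cooler` and `warmer`: scalar
#'   multipliers applied to all active coefficients in that season (or a
#'   named vector per predictor). 1 = season-invariant sources.
#' @param season_base named multipliers `c(cooler=, warmer=)` on the base
#'   level, capturing e.g. residential heating in the cooler months.
#' @param noise_sd hourly log-scale noise sd, independent per station-hour.
#' @param shared_sd sd of a log-scale hourly component shared by all
#'   stations (induces the cross-station correlation imputation exploits).
#' @param diurnal_amp amplitude of a deterministic log-scale diurnal cycle.
#' @param base_level base concentration in ppb, > 0.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(active = c("DIST.TACZ" = -2.5e-4, "GRS.300" = -4e-6),
                         seasonal_shift = list(cooler = 1, warmer = 1),
                         season_base = c(cooler = 1, warmer = 1),
                         noise_sd = 0.35, shared_sd = 0, diurnal_amp = 0,
                         base_level = 40) {
  if (base_level <= 0) stop("base_level must be positive")
  if (noise_sd < 0 || shared_sd < 0) stop("noise sds must be >= 0")
  for (nm in names(active)) {
    pr <- ppv_sign_prior(nm)
    if (pr == "+" && active[[nm]] < 0 || pr == "-" && active[[nm]] > 0)
      stop(sprintf("coefficient for %s must have sign '%s' per its class prior",
                   nm, pr))
  }
  structure(list(active = active, seasonal_shift = seasonal_shift,
                 season_base = season_base, noise_sd = noise_sd,
                 shared_sd = shared_sd, diurnal_amp = diurnal_amp,
                 base_level = base_level),
            class = "ground_truth")
}

#' Default paired ground truths for NO and NO2
#'
#' Cooler-season base multipliers follow the observed cooler/warmer median
#' ratios for nitrogen oxides in a heating-dominated city (about 2.3 for NO
#' and 1.4 for NO2).
#'
#' @param noise_sd,shared_sd log-scale noise levels, see [ground_truth()].
#' @return list with elements `no` and `no2`.
#' @export
default_truth <- function(noise_sd = 0.35, shared_sd = 0.25) {
  list(
    no = ground_truth(
      active = c("DIST.TACZ" = -3.0e-4, "LNDIST.PRSC" = 0.25,
                 "GRS.300" = -6e-6),
      season_base = c(cooler = 2.3, warmer = 1),
      noise_sd = noise_sd, shared_sd = shared_sd, diurnal_amp = 0.25,
      base_level = 15),
    no2 = ground_truth(
      active = c("OFIC.300" = 4e-6, "DIST.SNS" = -1.2e-4,
                 "LNDIST.PRSC" = 0.08),
      season_base = c(cooler = 1.4, warmer = 1),
      noise_sd = noise_sd, shared_sd = shared_sd, diurnal_amp = 0.15,
      base_level = 28))
}

#' Hourly timestamps for one calendar year
#' @param year calendar year (must not be a leap year: 8760 hours).
#' @export
hourly_timestamps <- function(year = 2010) {
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  ts <- t0 + (0:8759) * 3600
  if (format(ts[8760], "%Y") != as.character(year))
    stop("year must have 8760 hours (non-leap)")
  ts
}

season_of <- function(timestamps, warmer_months = 4:9) {
  ifelse(as.integer(format(timestamps, "%m")) %in% warmer_months,
         "warmer", "cooler")
}

shift_for <- function(truth, season, ppv_names) {
  s <- truth$seasonal_shift[[season]]
  if (length(s) == 1L && is.null(names(s))) rep(s, length(ppv_names))
  else as.numeric(s[ppv_names])
}

#' Simulate hourly station concentrations
#'
#' Hourly log concentration is
#' `log(base) + log(season_base) + sum(shift * coef * ppv) + diurnal +
#' shared + noise`; NO and NO2 are simulated from their own ground truths
#' and NOx is their sum at every hour (so NOx >= max(NO, NO2) always).
#'
#' @param scene a `city_scene`.
#' @param stations data.frame with station_id, x, y; all inside the scene.
#' @param truth a single [ground_truth()] (used for both NO and NO2) or a
#'   list with elements `no` and `no2`.
#' @param seed integer RNG seed.
#' @param year calendar year for the timestamps.
#' @return data.frame: station_id, timestamp, no, no2, nox (ppb).
#' @export
simulate_concentrations <- function(scene, stations, truth = default_truth(),
                                    seed = 1L, year = 2010) {
  if (inherits(truth, "ground_truth")) truth <- list(no = truth, no2 = truth)
  stopifnot(all(c("no", "no2") %in% names(truth)))
  ext <- scene$extent
  out_of <- stations$x < ext[1] | stations$x > ext[2] |
            stations$y < ext[3] | stations$y > ext[4]
  if (any(out_of))
    stop("stations outside the scene extent: ",
         paste(stations$station_id[out_of], collapse = ", "))
  set.seed(seed)
  ts <- hourly_timestamps(year)
  season <- season_of(ts)
  hour <- as.integer(format(ts, "%H"))
  n_h <- length(ts); n_s <- nrow(stations)

  ppv_names <- unique(c(names(truth$no$active), names(truth$no2$active)))
  xvals <- ppv_values_at(scene, stations, ppv_names)

  conc <- list()
  for (pol in c("no", "no2")) {
    tr <- truth[[pol]]
    lin <- rep(0, n_s)
    sbase <- log(tr$season_base[season])
    diurnal <- tr$diurnal_amp * sin(2 * pi * (hour - 9) / 24)
    shared <- if (tr$shared_sd > 0) stats::rnorm(n_h, 0, tr$shared_sd) else
      numeric(n_h)
    m <- matrix(0, n_h, n_s)
    for (si in seq_len(n_s)) {
      xs <- xvals[si, names(tr$active), drop = TRUE]
      # per-season coefficient multipliers
      sc <- vapply(c("cooler", "warmer"), function(s)
        sum(unlist(xs) * tr$active * shift_for(tr, s, names(tr$active))),
        numeric(1))
      mu <- log(tr$base_level) + sbase + unname(sc[season]) + diurnal + shared
      eps <- if (tr$noise_sd > 0) stats::rnorm(n_h, 0, tr$noise_sd) else 0
      m[, si] <- exp(mu + eps)
    }
    conc[[pol]] <- m
  }
  nox <- conc$no + conc$no2
  data.frame(
    station_id = rep(stations$station_id, each = n_h),
    timestamp = rep(ts, times = n_s),
    no = as.vector(conc$no), no2 = as.vector(conc$no2),
    nox = as.vector(nox), stringsAsFactors = FALSE)
}

#' Mask values in an hourly series
#'
#' `mcar` removes an exact count of uniformly random cells per station and
#' pollutant (realized missingness equals the requested rate up to
#' rounding); `block` removes contiguous instrument-outage gaps with
#' geometric lengths until the target rate is reached.
#'
#' @param series data.frame from [simulate_concentrations()].
#' @param rate scalar in [0, 1), or named vector per pollutant
#'   (e.g. `c(no = 0.281, no2 = 0.277, nox = 0.276)`).
#' @param mechanism `"mcar"` or `"block"`.
#' @param seed integer RNG seed.
#' @param mean_gap mean outage length in hours for the block mechanism.
#' @return the series with masked cells set to `NA`.
#' @export
apply_missingness <- function(series, rate, mechanism = c("mcar", "block"),
                              seed = 1L, mean_gap = 72) {
  mechanism <- match.arg(mechanism)
  pols <- intersect(c("no", "no2", "nox"), names(series))
  if (is.null(names(rate))) rate <- stats::setNames(rep(rate[[1]], length(pols)), pols)
  if (any(rate < 0) || any(rate >= 1)) stop("rate must be in [0, 1)")
  set.seed(seed)
  for (sid in unique(series$station_id)) {
    rows <- which(series$station_id == sid)
    n <- length(rows)
    for (p in pols) {
      r <- rate[[p]]
      if (r == 0) next
      if (mechanism == "mcar") {
        k <- round(r * n)
        drop <- sample.int(n, k)
      } else {
        miss <- logical(n)
        target <- r * n
        while (sum(miss) < target) {
          len <- 1L + stats::rgeom(1L, 1 / mean_gap)
          start <- sample.int(n, 1L)
          miss[start:min(n, start + len - 1L)] <- TRUE
        }
        drop <- which(miss)
      }
      series[rows[drop], p] <- NA_real_
    }
  }
  series
}

#' Write / read hourly series CSV
#'
#' Columns station_id, timestamp (ISO-8601 UTC), no, no2, nox; empty cells
#' are missing values.
#'
#' @param series hourly series data.frame.
#' @param path file path.
#' @export
write_hourly_csv <- function(series, path) {
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_hourly_csv
#' @export
read_hourly_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  df
}
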