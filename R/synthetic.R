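# Seed-controlled synthetic scenario generator: smooth spatial fields with
# temporal persistence, a regime-structured wind series, cloud-shaped
# satellite gaps, and an injectable wind-dependent anomaly plume, so every
# pipeline stage runs with no external data.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default per-feature field parameters
#'
#' Means, standard deviations and spatial correlation lengths loosely
#' typical of late-spring North Sea surface conditions (SST around 10 degC,
#' CHL around 2 mg/m3); configurable, with no claim of hydrodynamic
#' realism.
#'
#' @return Data frame with columns `feature`, `mean`, `sd`, `corr_deg`.
#' @export
default_feature_params <- function() {
  data.frame(
    feature  = c("SST", "CHL", "TSM", "u", "v", "T0", "S0"),
    mean     = c(10,    2,     1.5,   0.1, 0.05, 10,   32),
    sd       = c(0.6,   0.5,   0.4,   0.15, 0.15, 0.6, 0.3),
    corr_deg = c(0.05,  0.05,  0.05,  0.08, 0.08, 0.08, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Default wind regimes
#'
#' Six regimes over 31 days with a stable 10-day final regime, mirroring
#' the month-long regime structure of the study period (directions are
#' meteorological: where the wind comes from, degrees clockwise from
#' north).
#'
#' @return Data frame with columns `direction`, `speed`, `duration`.
#' @export
default_wind_regimes <- function() {
  data.frame(direction = c(315, 180, 45, 300, 135, 270),
             speed     = c(8,   12,  6,  10,  7,   9),
             duration  = c(5,   4,   3,  4,   5,   10))
}

#' Synthetic scenario configuration
#'
#' Defaults reproduce the study conditions: the DanTysk-area grid bounds
#' and 0.004 degree spacing (12,144 analysis points), 31 days, cloud gaps
#' on about 9 of 31 days, and a six-regime wind month. The farm footprint
#' defaults to a central rectangle covering roughly 3% of the area —
#' the size class of the expected effects.
#'
#' @param lat_min,lat_max,lon_min,lon_max Analysis-grid bounds (degrees).
#' @param spacing Analysis-grid spacing (degrees).
#' @param n_days Number of days.
#' @param features Per-feature parameters ([default_feature_params()]).
#' @param rho Temporal persistence of the fields, AR(1) coefficient in
#'   `[0, 1)`.
#' @param wind_regimes Regime table ([default_wind_regimes()]); durations
#'   must sum to `n_days`.
#' @param wind_angle_noise_sd Wrapped-normal direction noise, degrees.
#' @param cloud List: `day_prob` (probability a day has cloud gaps),
#'   `n_blobs`, `radius_km`.
#' @param plume List: `enabled`, `magnitudes` (named vector, perturbation
#'   per feature in units of that feature's sd), `radius_km`,
#'   `offset_km` (displacement of the plume centre downwind of the farm
#'   centroid), and optional `wind_gate` (m/s): when set, the plume is
#'   active only on days whose regime wind speed reaches the gate —
#'   wake-induced mixing driven by strong winds — giving episodic rather
#'   than permanent perturbations.
#' @param satellite_spacing,model_spacing Source-raster spacings (degrees);
#'   source grids are offset from the analysis grid by a third of a pixel.
#' @param model_hours Hours of day at which model samples are emitted
#'   (hourly cadence around the daily overpass).
#' @param overpass_hour Satellite overpass hour (decimal hours UTC).
#' @param seed Integer seed fixing all randomness.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(lat_min = 54.97, lat_max = 55.32,
                            lon_min = 6.92, lon_max = 7.47,
                            spacing = 0.004, n_days = 31,
                            features = default_feature_params(),
                            rho = 0.7,
                            wind_regimes = default_wind_regimes(),
                            wind_angle_noise_sd = 8,
                            cloud = list(day_prob = 9 / 31, n_blobs = 3,
                                         radius_km = 6),
                            plume = list(enabled = FALSE,
                                         magnitudes = c(SST = 3, T0 = 3),
                                         radius_km = 4, offset_km = 5,
                                         wind_gate = NULL),
                            satellite_spacing = spacing,
                            model_spacing = 0.009,
                            model_hours = 9:11,
                            overpass_hour = 10,
                            seed = 1) {
  if (sum(wind_regimes$duration) != n_days)
    stop("scenario_config: regime durations must sum to n_days")
  stopifnot(rho >= 0, rho < 1,
            all(is.finite(plume$magnitudes)))
  cfg <- list(lat_min = lat_min, lat_max = lat_max,
              lon_min = lon_min, lon_max = lon_max,
              spacing = spacing, n_days = n_days,
              features = features, rho = rho,
              wind_regimes = wind_regimes,
              wind_angle_noise_sd = wind_angle_noise_sd,
              cloud = cloud, plume = plume,
              satellite_spacing = satellite_spacing,
              model_spacing = model_spacing,
              model_hours = model_hours,
              overpass_hour = overpass_hour,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

# Separable Gaussian smoothing with sd `sigma` cells. The input is
# expected to carry a margin of at least 3 sigma cells so no kernel
# renormalisation (and hence no edge-variance inflation) is needed on the
# region of interest.
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  kern <- function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + x
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    K
  }
  kern(nrow(m)) %*% m %*% t(kern(ncol(m)))
}

#' Generate one smooth spatial field realisation
#'
#' Gaussian random field realised as Gaussian-smoothed white noise with the
#' stated correlation length, standardised to zero mean and unit variance.
#' Consecutive days are blended as an AR(1) process at persistence `rho`
#' (handled by the caller via `prev`).
#'
#' @param n_lat,n_lon Field dimensions (rows = latitudes).
#' @param corr_cells Correlation length in grid cells (Gaussian sd).
#' @param prev Previous day's standardised field, or `NULL` for the first
#'   day.
#' @param rho AR(1) persistence in `[0, 1)`.
#' @return n_lat x n_lon standardised field matrix.
#' @export
gaussian_field <- function(n_lat, n_lon, corr_cells, prev = NULL, rho = 0) {
  # smooth on a padded grid and crop, so edge cells keep the same
  # variance as the interior
  pad <- if (corr_cells > 0) ceiling(3 * corr_cells) else 0L
  z <- smooth_matrix(matrix(stats::rnorm((n_lat + 2 * pad) *
                                           (n_lon + 2 * pad)),
                            n_lat + 2 * pad, n_lon + 2 * pad),
                     corr_cells)
  z <- z[pad + seq_len(n_lat), pad + seq_len(n_lon), drop = FALSE]
  s <- stats::sd(as.numeric(z))
  if (is.finite(s) && s > 0) z <- (z - mean(z)) / s
  if (!is.null(prev)) z <- rho * prev + sqrt(1 - rho^2) * z
  z
}

# Daily regime lookup: one row per day.
regime_by_day <- function(regimes, n_days) {
  idx <- rep(seq_len(nrow(regimes)), regimes$duration)
  data.frame(day = seq_len(n_days),
             direction = regimes$direction[idx],
             speed = regimes$speed[idx])
}

# Displace (lat, lon) by dist_km along a compass bearing (0 = north).
displace_km <- function(lat, lon, bearing_deg, dist_km) {
  deg_per_km <- 180 / (pi * EARTH_RADIUS_KM)
  b <- bearing_deg * pi / 180
  c(lat = lat + dist_km * cos(b) * deg_per_km,
    lon = lon + dist_km * sin(b) * deg_per_km / cos(lat * pi / 180))
}

#' Perturb observations inside a plume disc
#'
#' Adds `delta` (same units as the values) to every observation within
#' `radius_km` of the centre: the full `delta` over the flat disc core
#' (inner 60% of the radius), rolled off smoothly to zero at the edge by a
#' raised cosine.
#'
#' @param obs Data frame with `lat`, `lon`, `value`.
#' @param center `c(lat, lon)` of the disc centre.
#' @param radius_km Disc radius, km.
#' @param delta Perturbation over the disc core.
#' @param core Fraction of the radius over which the perturbation is flat.
#' @return The perturbed data frame.
#' @export
inject_plume <- function(obs, center, radius_km, delta, core = 0.6) {
  if (delta == 0 || nrow(obs) == 0) return(obs)
  d <- haversine_km(obs$lat, obs$lon, center[[1]], center[[2]])
  inside <- d <= radius_km
  u <- d[inside] / radius_km
  taper <- ifelse(u <= core, 1,
                  0.5 * (1 + cos(pi * (u - core) / (1 - core))))
  obs$value[inside] <- obs$value[inside] + delta * taper
  obs
}

#' Mask observations under cloud discs
#'
#' Sets values within any of the given discs to `NA` — the satellite
#' product's fill under cloud — so nearest-neighbour resampling adopts the
#' missing value and the gap propagates to the grid.
#'
#' @param obs Data frame with `lat`, `lon`, `value`.
#' @param discs Data frame with `lat`, `lon`, `radius_km`, one row per
#'   cloud blob (zero rows = no masking).
#' @return The masked data frame.
#' @export
inject_clouds <- function(obs, discs) {
  for (i in seq_len(NROW(discs))) {
    d <- haversine_km(obs$lat, obs$lon, discs$lat[i], discs$lon[i])
    obs$value[d <= discs$radius_km[i]] <- NA_real_
  }
  obs
}

#' Rectangular farm footprint polygon
#'
#' Default wind-farm footprint: a rectangle centred in the scenario bounds
#' covering about 3% of the study area.
#'
#' @param cfg A `scenario_config`.
#' @param frac Linear fraction of each bound span (default 0.18, i.e.
#'   about 3.2% of the area).
#' @return Data frame of polygon vertices (`lat`, `lon`), closed ring.
#' @export
farm_polygon <- function(cfg, frac = 0.18) {
  clat <- (cfg$lat_min + cfg$lat_max) / 2
  clon <- (cfg$lon_min + cfg$lon_max) / 2
  hlat <- frac * (cfg$lat_max - cfg$lat_min) / 2
  hlon <- frac * (cfg$lon_max - cfg$lon_min) / 2
  data.frame(lat = c(clat - hlat, clat - hlat, clat + hlat, clat + hlat,
                     clat - hlat),
             lon = c(clon - hlon, clon + hlon, clon + hlon, clon - hlon,
                     clon - hlon))
}

polygon_centroid <- function(poly) {
  k <- nrow(poly) - 1  # closed ring
  c(lat = mean(poly$lat[seq_len(k)]), lon = mean(poly$lon[seq_len(k)]))
}

source_grid_df <- function(cfg, spacing) {
  off <- spacing / 3  # source pixels deliberately off the analysis grid
  lats <- seq(cfg$lat_min + off, cfg$lat_max, by = spacing)
  lons <- seq(cfg$lon_min + off, cfg$lon_max, by = spacing)
  data.frame(lat = rep(lats, each = length(lons)),
             lon = rep(lons, times = length(lats)))
}

#' Generate a complete synthetic scenario
#'
#' Produces, under one seed: daily satellite scenes (SST, CHL, TSM on their
#' own pixel grid, cloud gaps shared across the three), hourly model
#' samples (u, v, T0, S0 on a coarser grid) around the overpass, a 10-min
#' wind series following the regime table with angular noise, the farm
#' polygon, and — when the plume is enabled — a perturbation disc displaced
#' downwind (regime direction + 180 degrees) of the farm centroid, with the
#' ground truth recorded for recovery tests.
#'
#' @param cfg A `scenario_config`.
#' @return A `scenario`: list with `sources` (list of [ww_source()]),
#'   `grid` (the analysis `grid_definition`), `farm` (polygon data frame),
#'   `truth` (regimes by day, plume centres and parameters, cloud discs by
#'   day), and `config`.
#' @export
generate_scenario <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(cfg$seed, generate_scenario_impl(cfg))
}

generate_scenario_impl <- function(cfg) {
  grid <- build_grid(cfg$lat_min, cfg$lat_max, cfg$lon_min, cfg$lon_max,
                     cfg$spacing)
  farm <- farm_polygon(cfg)
  fc <- polygon_centroid(farm)
  daily <- regime_by_day(cfg$wind_regimes, cfg$n_days)
  fp <- cfg$features

  plume_on <- isTRUE(cfg$plume$enabled)
  plume_centers <- if (plume_on) {
    t(vapply(seq_len(cfg$n_days), function(d)
      displace_km(fc[["lat"]], fc[["lon"]],
                  daily$direction[d] + 180, cfg$plume$offset_km),
      numeric(2)))
  } else NULL
  plume_active <- if (plume_on) {
    if (is.null(cfg$plume$wind_gate)) rep(TRUE, cfg$n_days)
    else daily$speed >= cfg$plume$wind_gate
  } else rep(FALSE, cfg$n_days)

  # cloud discs per day (shared by the three satellite features)
  clouds <- lapply(seq_len(cfg$n_days), function(d) {
    if (stats::runif(1) >= cfg$cloud$day_prob)
      return(data.frame(lat = numeric(0), lon = numeric(0),
                        radius_km = numeric(0)))
    nb <- cfg$cloud$n_blobs
    data.frame(
      lat = stats::runif(nb, cfg$lat_min, cfg$lat_max),
      lon = stats::runif(nb, cfg$lon_min, cfg$lon_max),
      radius_km = cfg$cloud$radius_km * stats::runif(nb, 0.6, 1.4))
  })

  sat_grid <- source_grid_df(cfg, cfg$satellite_spacing)
  mod_grid <- source_grid_df(cfg, cfg$model_spacing)
  sat_dims <- c(length(unique(sat_grid$lat)), length(unique(sat_grid$lon)))
  mod_dims <- c(length(unique(mod_grid$lat)), length(unique(mod_grid$lon)))

  make_raster_source <- function(feature, src_grid, dims, sat) {
    par <- fp[fp$feature == feature, ]
    sigma <- par$corr_deg / (if (sat) cfg$satellite_spacing
                             else cfg$model_spacing)
    prev <- NULL
    rows <- vector("list", cfg$n_days)
    for (d in seq_len(cfg$n_days)) {
      z <- gaussian_field(dims[1], dims[2], sigma, prev, cfg$rho)
      prev <- z
      # row-major to match src_grid ordering (lat outer, lon inner)
      vals <- par$mean + par$sd * as.numeric(t(z))
      obs <- data.frame(lat = src_grid$lat, lon = src_grid$lon,
                        value = vals)
      if (plume_active[d]) {
        mag <- cfg$plume$magnitudes[feature]
        if (!is.na(mag) && mag != 0)
          obs <- inject_plume(obs, plume_centers[d, ],
                              cfg$plume$radius_km, mag * par$sd)
      }
      if (sat) {
        obs <- inject_clouds(obs, clouds[[d]])
        obs$time <- (d - 1) * 86400 + cfg$overpass_hour * 3600
        rows[[d]] <- obs
      } else {
        rows[[d]] <- do.call(rbind, lapply(cfg$model_hours, function(h) {
          o <- obs
          o$value <- o$value + stats::rnorm(nrow(o), 0, 0.05 * par$sd)
          o$time <- (d - 1) * 86400 + h * 3600
          o
        }))
      }
    }
    ww_source(feature, do.call(rbind, rows))
  }

  sat_feats <- intersect(fp$feature, c("SST", "CHL", "TSM"))
  mod_feats <- setdiff(fp$feature, sat_feats)
  sources <- c(
    lapply(sat_feats, make_raster_source, src_grid = sat_grid,
           dims = sat_dims, sat = TRUE),
    lapply(mod_feats, make_raster_source, src_grid = mod_grid,
           dims = mod_dims, sat = FALSE)
  )

  # 10-min wind series following the regimes, with angular + speed noise
  steps_per_day <- 144L
  nt <- cfg$n_days * steps_per_day
  t_sec <- (seq_len(nt) - 1) * 600
  day_ix <- pmin(day_of_time(t_sec), cfg$n_days)
  dir_series <- (daily$direction[day_ix] +
                 stats::rnorm(nt, 0, cfg$wind_angle_noise_sd)) %% 360
  spd_series <- pmax(0.3, daily$speed[day_ix] + stats::rnorm(nt, 0, 0.8))
  sources <- c(sources, list(
    ww_source("wind_speed", data.frame(time = t_sec, value = spd_series)),
    ww_source("wind_direction", data.frame(time = t_sec,
                                           value = dir_series))))

  truth <- list(
    regimes_by_day = daily,
    plume = if (plume_on) list(
      centers = data.frame(day = seq_len(cfg$n_days),
                           lat = plume_centers[, 1],
                           lon = plume_centers[, 2],
                           active = plume_active),
      features = names(cfg$plume$magnitudes)[cfg$plume$magnitudes != 0],
      magnitudes = cfg$plume$magnitudes,
      radius_km = cfg$plume$radius_km,
      offset_km = cfg$plume$offset_km) else NULL,
    clouds = clouds,
    farm_centroid = fc
  )
  structure(list(sources = sources, grid = grid, farm = farm,
                 truth = truth, config = cfg),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d days, %d sources, grid %d points, seed %d\n",
              x$config$n_days, length(x$sources), x$grid$n_points,
              x$config$seed))
  if (!is.null(x$truth$plume))
    cat(sprintf("  plume: %s at %g sd, r=%g km, offset %g km downwind\n",
                paste(x$truth$plume$features, collapse = "+"),
                max(x$truth$plume$magnitudes), x$truth$plume$radius_km,
                x$truth$plume$offset_km))
  invisible(x)
}

#' Fuse a scenario's sources onto its analysis grid
#'
#' @param scenario A `scenario`.
#' @param ... Passed to [fuse()].
#' @return A `fused_cube`.
#' @export
fuse_scenario <- function(scenario, ...) {
  fuse(scenario$sources, scenario$grid, scenario$config$n_days,
       windows = overpass_windows(scenario$config$n_days,
                                  scenario$config$overpass_hour), ...)
}

#' Daily wind summary of a scenario
#'
#' Circular-mean direction and mean speed per day from the 10-min series,
#' as used for window segmentation.
#'
#' @param scenario A `scenario`.
#' @return Data frame `day`, `direction`, `speed`.
#' @export
scenario_daily_wind <- function(scenario) {
  ws <- scenario$sources[[which(vapply(scenario$sources,
                                       function(s) s$feature,
                                       character(1)) == "wind_speed")]]
  wd <- scenario$sources[[which(vapply(scenario$sources,
                                       function(s) s$feature,
                                       character(1)) == "wind_direction")]]
  n <- scenario$config$n_days
  day_s <- day_of_time(wd$data$time)
  data.frame(
    day = seq_len(n),
    direction = vapply(seq_len(n), function(d)
      circular_mean_deg(wd$data$value[day_s == d]), numeric(1)),
    speed = vapply(seq_len(n), function(d)
      mean(ws$data$value[day_of_time(ws$data$time) == d]), numeric(1)))
}
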