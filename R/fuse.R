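# Source registry, temporal alignment, and fusion onto the common grid.

#' The variable registry
#'
#' The fixed set of sea-surface variables the pipeline knows about, with
#' units, source class (satellite raster, model raster, or in-situ point
#' measurement) and whether the variable is a compass direction (and must be
#' averaged circularly).
#'
#' @return Data frame with columns `feature`, `unit`, `source_class`,
#'   `directional`.
#' @export
feature_registry <- function() {
  data.frame(
    feature = c("SST", "CHL", "TSM",
                "u", "v", "current_direction", "T0", "S0",
                "wind_speed", "wind_direction"),
    unit = c("degC", "mg m-3", "g m-3",
             "m s-1", "m s-1", "deg", "degC", "psu",
             "m s-1", "deg"),
    source_class = c("satellite", "satellite", "satellite",
                     "model", "model", "model", "model", "model",
                     "in_situ", "in_situ"),
    directional = c(FALSE, FALSE, FALSE,
                    FALSE, FALSE, TRUE, FALSE, FALSE,
                    FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

registry_row <- function(feature) {
  reg <- feature_registry()
  i <- match(feature, reg$feature)
  if (is.na(i)) stop(sprintf("unregistered feature '%s'", feature))
  reg[i, ]
}

#' Construct a data source for fusion
#'
#' Wraps one feature's observations with its registry metadata. Satellite
#' and model sources carry georeferenced samples (`time`, `lat`, `lon`,
#' `value`); in-situ sources are point measurements (`time`, `value`) that
#' are broadcast to the whole grid.
#'
#' @param feature Registered feature name.
#' @param data Data frame of observations. Columns `time` (numeric seconds
#'   or POSIXct) and `value` are required; `lat`/`lon` are required for
#'   satellite and model sources.
#' @return A `ww_source` object.
#' @export
ww_source <- function(feature, data) {
  reg <- registry_row(feature)
  need <- if (reg$source_class == "in_situ") c("time", "value")
          else c("time", "lat", "lon", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop(sprintf("source '%s': missing columns %s", feature,
                 paste(miss, collapse = ", ")))
  data$time <- as.numeric(data$time)
  data <- data[order(data$time), , drop = FALSE]
  structure(list(feature = feature,
                 source_class = reg$source_class,
                 directional = reg$directional,
                 data = data),
            class = "ww_source")
}

#' Daily overpass windows on the pipeline's internal clock
#'
#' The pipeline's time axis is seconds from the start of day 1; day `d`
#' spans `[(d-1)*86400, d*86400)`. The satellite overpass is the daily
#' temporal reference: sub-daily sources are averaged over a window centred
#' on the overpass time.
#'
#' @param n_days Number of days.
#' @param center_hour Overpass hour-of-day (UTC decimal hours, default 10).
#' @param width_min Window width in minutes (default 60).
#' @return `n_days` x 2 matrix of window `[start, end]` times in seconds.
#' @export
overpass_windows <- function(n_days, center_hour = 10, width_min = 60) {
  stopifnot(n_days >= 1, width_min > 0)
  center <- (seq_len(n_days) - 1) * 86400 + center_hour * 3600
  half <- width_min * 60 / 2
  cbind(start = center - half, end = center + half)
}

day_of_time <- function(time) floor(as.numeric(time) / 86400) + 1

#' Fuse heterogeneous sources onto the common grid and daily time base
#'
#' Builds the pipeline's central data structure: a day x grid-point x
#' feature cube. Satellite features (one scene per day) are resampled onto
#' the grid by Haversine nearest neighbour with a 1 km cutoff; model
#' features are first averaged per location over the daily overpass window,
#' then resampled the same way; in-situ features are averaged over the
#' window and broadcast to every grid point. All gaps are recorded in the
#' cube's missingness mask.
#'
#' @param sources List of `ww_source` objects, one feature each; duplicate
#'   features are an error.
#' @param grid A `grid_definition`.
#' @param n_days Number of days in the cube.
#' @param windows Overpass windows from [overpass_windows()] (default:
#'   10:00 UTC, 60 min).
#' @param cutoff_km Nearest-neighbour adoption cutoff in km.
#' @return A `fused_cube`.
#' @export
fuse <- function(sources, grid, n_days,
                 windows = overpass_windows(n_days), cutoff_km = 1.0) {
  stopifnot(inherits(grid, "grid_definition"), n_days >= 1)
  feats <- vapply(sources, function(s) s$feature, character(1))
  if (anyDuplicated(feats))
    stop("fuse: duplicate feature names across sources")
  values <- array(NA_real_,
                  dim = c(n_days, grid$n_points, length(feats)),
                  dimnames = list(NULL, NULL, feats))
  for (s in sources) {
    f <- s$feature
    for (d in seq_len(n_days)) {
      if (s$source_class == "in_situ") {
        v <- align_to_overpass(s$data$time, s$data$value,
                               windows[d, , drop = FALSE],
                               circular = s$directional)
        values[d, , f] <- broadcast_point_source(v, grid)
      } else {
        rows <- if (s$source_class == "satellite") {
          s$data[day_of_time(s$data$time) == d, , drop = FALSE]
        } else {
          s$data[s$data$time >= windows[d, 1] &
                 s$data$time <= windows[d, 2], , drop = FALSE]
        }
        if (nrow(rows) == 0) next
        agg <- collapse_by_location(rows, s$directional)
        values[d, , f] <- resample_nearest(agg, grid, cutoff_km)
      }
    }
  }
  fused_cube(values, grid)
}

# Average repeated samples per (lat, lon) location; circular for directions.
collapse_by_location <- function(rows, directional) {
  key <- paste(rows$lat, rows$lon, sep = "|")
  if (!anyDuplicated(key)) return(rows[, c("lat", "lon", "value")])
  groups <- split(seq_len(nrow(rows)), key)
  # preserve first-appearance order so tie-breaking stays deterministic
  groups <- groups[order(vapply(groups, min, integer(1)))]
  do.call(rbind, lapply(groups, function(ix) {
    v <- rows$value[ix]
    v <- v[is.finite(v)]
    data.frame(lat = rows$lat[ix[1]], lon = rows$lon[ix[1]],
               value = if (length(v) == 0) NA_real_
                       else if (directional) circular_mean_deg(v)
                       else mean(v))
  }))
}

#' Construct a fused cube from a value array
#'
#' @param values day x point x feature array; `NA` marks missing. The third
#'   dimension must carry registered feature names.
#' @param grid The `grid_definition` the points refer to.
#' @return A `fused_cube`: list with `values`, logical `mask` (TRUE =
#'   missing), `grid`, `n_days`, `features`.
#' @export
fused_cube <- function(values, grid) {
  stopifnot(length(dim(values)) == 3,
            inherits(grid, "grid_definition"),
            dim(values)[2] == grid$n_points)
  feats <- dimnames(values)[[3]]
  if (is.null(feats)) stop("fused_cube: feature dimension must be named")
  reg <- feature_registry()
  unknown <- setdiff(feats, reg$feature)
  if (length(unknown))
    stop(sprintf("fused_cube: unregistered features: %s",
                 paste(unknown, collapse = ", ")))
  structure(list(values = values,
                 mask = is.na(values),
                 grid = grid,
                 n_days = dim(values)[1],
                 features = feats),
            class = "fused_cube")
}

#' @export
print.fused_cube <- function(x, ...) {
  cat(sprintf("<fused_cube> %d days x %d points x %d features\n",
              x$n_days, x$grid$n_points, length(x$features)))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  missing: %.1f%% of entries\n", 100 * mean(x$mask)))
  invisible(x)
}

#' Per-day count of missing features at each grid point
#'
#' The cube-level missingness summary used to inspect cloud footprints: for
#' each day and grid point, how many features are missing.
#'
#' @param cube A `fused_cube`.
#' @return day x point integer matrix.
#' @export
missing_feature_counts <- function(cube) {
  stopifnot(inherits(cube, "fused_cube"))
  apply(cube$mask, c(1, 2), sum)
}
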