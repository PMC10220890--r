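# Common-grid construction and Haversine geometry.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance between two points (Haversine formula)
#'
#' Distance in kilometres on a sphere of radius 6371 km between
#' latitude/longitude pairs given in decimal degrees. Vectorised over all
#' four arguments with the usual recycling rules.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(55.195, 7.158, 55.199, 7.158)
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(!is.finite(c(lat1, lon1, lat2, lon2))))
    stop("haversine_km: coordinates must be finite")
  if (any(abs(c(lat1, lat2)) > 90))
    stop("haversine_km: latitudes must lie in [-90, 90]")
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Build the common analysis grid
#'
#' Generates a regular latitude/longitude grid covering the study area.
#' Coordinates run from the lower bound in steps of `spacing`, keeping every
#' coordinate that does not exceed the upper bound (with a 1e-9 degree
#' floating-point tolerance, so a bound that is an exact multiple of the
#' spacing is included). Points are indexed row-major from the south-west
#' corner: index 1 is (lat_min, lon_min), index 2 is (lat_min, lon_min +
#' spacing), and so on.
#'
#' The DanTysk study area (54.97--55.32 N, 6.92--7.47 E at 0.004 degree
#' spacing) yields an 88 x 138 grid of 12,144 points.
#'
#' @param lat_min,lat_max,lon_min,lon_max Grid bounds, decimal degrees.
#' @param spacing Grid spacing in degrees, identical for both axes.
#' @return A `grid_definition` object: list with the bounds, `spacing`,
#'   `n_lat`, `n_lon`, `n_points`, and vectors `lat`, `lon` of per-point
#'   coordinates (length `n_points`).
#' @examples
#' g <- build_grid(54.97, 55.32, 6.92, 7.47, 0.004)
#' g$n_points # 12144
#' @export
build_grid <- function(lat_min, lat_max, lon_min, lon_max, spacing) {
  stopifnot(is.numeric(spacing), length(spacing) == 1, spacing > 0)
  if (!(lat_min < lat_max) || !(lon_min < lon_max))
    stop("build_grid: bounds must be ordered (min < max)")
  tol <- 1e-9
  n_lat <- floor((lat_max - lat_min) / spacing + tol) + 1
  n_lon <- floor((lon_max - lon_min) / spacing + tol) + 1
  if (n_lat < 1 || n_lon < 1) stop("build_grid: empty grid")
  lats <- lat_min + (seq_len(n_lat) - 1) * spacing
  lons <- lon_min + (seq_len(n_lon) - 1) * spacing
  g <- list(
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max,
    spacing = spacing,
    n_lat = n_lat, n_lon = n_lon,
    n_points = n_lat * n_lon,
    # row-major: all longitudes for the first latitude, then the next row
    lat = rep(lats, each = n_lon),
    lon = rep(lons, times = n_lat)
  )
  class(g) <- "grid_definition"
  g
}

#' @export
print.grid_definition <- function(x, ...) {
  cat(sprintf(
    "<grid_definition> %d points (%d lat x %d lon), spacing %g deg\n",
    x$n_points, x$n_lat, x$n_lon, x$spacing))
  cat(sprintf("  lat %g..%g  lon %g..%g\n",
              x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

#' Nearest-neighbour resampling of point observations onto the grid
#'
#' Each grid point adopts the value of its nearest observation (Haversine
#' distance, k = 1) provided that observation lies within `cutoff_km`;
#' otherwise the point is left missing. When two observations are exactly
#' equidistant the one with the lower index wins, making the result
#' deterministic.
#'
#' @param obs Data frame with columns `lat`, `lon`, `value`: one feature at
#'   one time slot. May have zero rows, giving a fully missing field.
#' @param grid A `grid_definition`.
#' @param cutoff_km Maximum adoption distance in km (default 1).
#' @return Numeric vector of length `grid$n_points`; `NA` where no
#'   observation lies within the cutoff.
#' @export
resample_nearest <- function(obs, grid, cutoff_km = 1.0) {
  stopifnot(inherits(grid, "grid_definition"))
  out <- rep(NA_real_, grid$n_points)
  if (is.null(obs) || nrow(obs) == 0) return(out)
  # chunk over grid points to bound the distance-matrix size
  n <- grid$n_points
  m <- nrow(obs)
  chunk <- max(1L, floor(4e6 / m))
  start <- 1L
  while (start <= n) {
    idx <- start:min(n, start + chunk - 1L)
    d <- outer(idx, seq_len(m), function(i, j)
      haversine_km(grid$lat[i], grid$lon[i], obs$lat[j], obs$lon[j]))
    nearest <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_along(idx), nearest)]
    ok <- dmin <= cutoff_km
    out[idx[ok]] <- obs$value[nearest[ok]]
    start <- start + chunk
  }
  out
}

#' Broadcast a point measurement to every grid point
#'
#' In-situ sources (e.g. platform wind) are point measurements carrying the
#' area's weather: every grid point adopts the same value. A missing input
#' gives a fully missing field.
#'
#' @param value Single numeric value (may be `NA`).
#' @param grid A `grid_definition`.
#' @return Numeric vector of length `grid$n_points`.
#' @export
broadcast_point_source <- function(value, grid) {
  stopifnot(inherits(grid, "grid_definition"), length(value) == 1)
  if (!is.finite(value)) return(rep(NA_real_, grid$n_points))
  rep(as.numeric(value), grid$n_points)
}

#' Circular mean of directions in degrees
#'
#' Mean direction of angles on the compass circle, computed from the vector
#' sum of unit vectors; result in [0, 360). Returns `NA` for an empty input
#' or when the resultant vector length is numerically zero (e.g. two
#' opposite directions).
#'
#' @param deg Numeric vector of directions in degrees.
#' @return Mean direction in degrees.
#' @export
circular_mean_deg <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0) return(NA_real_)
  s <- mean(sin(deg * pi / 180))
  c <- mean(cos(deg * pi / 180))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  r <- (atan2(s, c) * 180 / pi) %% 360
  if (r > 360 - 1e-9) 0 else r
}

# Smallest angular distance between two directions, degrees in [0, 180].
angular_distance_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Collapse a sub-daily series to one value per day at the satellite overpass
#'
#' Reduces a timestamped series to the daily reference time base: for each
#' day, the arithmetic mean of the samples falling inside that day's
#' overpass window (circular mean for direction-typed features, which
#' otherwise average wrongly across the 0/360 wrap). A day whose window
#' contains no samples is missing.
#'
#' @param time Sorted numeric timestamps (seconds since an arbitrary epoch)
#'   or `POSIXct`.
#' @param value Sample values, same length as `time`.
#' @param windows Two-column matrix (or data frame) of window start/end
#'   times, one row per day, same units as `time`; windows are inclusive.
#' @param circular Logical: average as compass directions?
#' @return Numeric vector, one value per row of `windows` (`NA` = missing).
#' @export
align_to_overpass <- function(time, value, windows, circular = FALSE) {
  time <- as.numeric(time)
  stopifnot(length(time) == length(value))
  if (is.unsorted(time)) stop("align_to_overpass: timestamps must be sorted")
  windows <- as.matrix(windows)
  if (ncol(windows) != 2 || any(windows[, 1] > windows[, 2]))
    stop("align_to_overpass: windows must be [start, end] with start <= end")
  vapply(seq_len(nrow(windows)), function(i) {
    sel <- time >= windows[i, 1] & time <= windows[i, 2]
    v <- value[sel]
    v <- v[is.finite(v)]
    if (length(v) == 0) return(NA_real_)
    if (circular) circular_mean_deg(v) else mean(v)
  }, numeric(1))
}

#' Spherical area of a latitude/longitude bounding box
#'
#' Area in square kilometres of the box between two parallels and two
#' meridians on a sphere of radius 6371 km.
#'
#' @param lat_min,lat_max,lon_min,lon_max Bounds in decimal degrees.
#' @return Area in km^2.
#' @export
bbox_area_km2 <- function(lat_min, lat_max, lon_min, lon_max) {
  stopifnot(lat_min < lat_max, lon_min < lon_max)
  dlam <- (lon_max - lon_min) * pi / 180
  EARTH_RADIUS_KM^2 * dlam *
    abs(sin(lat_max * pi / 180) - sin(lat_min * pi / 180))
}
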