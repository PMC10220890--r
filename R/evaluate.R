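# From raw score fields to interpretable anomaly maps: daily top-fraction
# selection scaled by score dispersion, 0-1 normalisation, wind-direction
# time windows, window averaging, persistence and cluster geometry.

#' Selection configuration
#'
#' The daily selection keeps the highest-scoring fraction of grid points —
#' by default the top 3%, matching the wind-farm-sized footprint of the
#' expected effects (369 of 12,144 points at the study grid). When
#' `scale_by_std` is on, the day's selected count is scaled by the ratio of
#' that day's score standard deviation to the month's mean daily standard
#' deviation, so a day with strongly dispersed scores contributes more
#' points than a steady day.
#'
#' @param base_fraction Fraction of points selected per day (default 0.03).
#' @param scale_by_std Scale the daily count by score dispersion?
#' @param farm_equivalent_points Optional integer overriding
#'   `base_fraction * N` as the unscaled daily count (the wind-farm size
#'   equivalent in grid points).
#' @return A `selection_config`.
#' @export
selection_config <- function(base_fraction = 0.03, scale_by_std = TRUE,
                             farm_equivalent_points = NULL) {
  stopifnot(base_fraction > 0, base_fraction <= 1)
  structure(list(base_fraction = base_fraction,
                 scale_by_std = isTRUE(scale_by_std),
                 farm_equivalent_points = farm_equivalent_points),
            class = "selection_config")
}

#' Select and normalise the top anomaly scores of one day
#'
#' Selects the `m` highest-scoring points (ties broken by lower index) with
#' `m = round(base * daily_std / month_mean_std)` clipped to `[1, N]`,
#' where `base` is `base_fraction * N` (or the farm-equivalent override);
#' with scaling off, `m = round(base)`. Selected scores are min-max
#' normalised to [0, 1] (all 1 when the selected scores are constant);
#' unselected points carry 0.
#'
#' @param scores_day Per-point score vector for one day.
#' @param cfg A `selection_config`.
#' @param daily_std Standard deviation of this day's scores.
#' @param month_mean_std Mean of the daily standard deviations over the
#'   period.
#' @return List with `selected` (indices) and `map` (per-point normalised
#'   values, 0 where unselected).
#' @export
select_top <- function(scores_day, cfg = selection_config(),
                       daily_std = stats::sd(scores_day),
                       month_mean_std = daily_std) {
  n <- length(scores_day)
  stopifnot(n >= 1)
  base <- if (!is.null(cfg$farm_equivalent_points))
    cfg$farm_equivalent_points else cfg$base_fraction * n
  m <- if (cfg$scale_by_std && is.finite(daily_std) &&
           is.finite(month_mean_std) && month_mean_std > 0)
    round(base * daily_std / month_mean_std) else round(base)
  m <- min(max(m, 1L), n)
  ord <- order(-scores_day, seq_len(n))
  sel <- sort(ord[seq_len(m)])
  v <- scores_day[sel]
  rng <- range(v)
  norm <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
          else rep(1, length(v))
  map <- numeric(n)
  map[sel] <- norm
  list(selected = sel, map = map)
}

#' Segment the day axis into windows of similar wind direction
#'
#' Greedy left-to-right segmentation of a daily wind-direction series: a
#' new window starts when the angular distance between a day's direction
#' and the running circular mean of the current window exceeds
#' `angle_threshold`. Windows partition the day axis; single-day windows
#' are allowed (weather can change quickly).
#'
#' @param direction_deg One wind direction per day, degrees (circular mean
#'   of the sub-daily measurements).
#' @param angle_threshold Break threshold in degrees (default 45).
#' @return Data frame with one row per window: `start_day`, `end_day`
#'   (inclusive), `mean_direction` (circular, degrees).
#' @export
segment_windows <- function(direction_deg, angle_threshold = 45) {
  n <- length(direction_deg)
  if (n == 0) stop("segment_windows: empty series")
  starts <- integer(0); ends <- integer(0); means <- numeric(0)
  cur_start <- 1L
  cur_dirs <- direction_deg[1]
  for (d in seq_len(n)[-1]) {
    mu <- circular_mean_deg(cur_dirs)
    if (is.finite(direction_deg[d]) && is.finite(mu) &&
        angular_distance_deg(direction_deg[d], mu) > angle_threshold) {
      starts <- c(starts, cur_start); ends <- c(ends, d - 1L)
      means <- c(means, mu)
      cur_start <- d
      cur_dirs <- direction_deg[d]
    } else {
      cur_dirs <- c(cur_dirs, direction_deg[d])
    }
  }
  starts <- c(starts, cur_start); ends <- c(ends, n)
  means <- c(means, circular_mean_deg(cur_dirs))
  data.frame(start_day = starts, end_day = ends, mean_direction = means)
}

#' Average daily selection maps over a time window
#'
#' Per-point arithmetic mean of the normalised daily maps; days on which a
#' point was unselected contribute 0.
#'
#' @param maps day x point matrix of normalised daily selection maps.
#' @return Per-point averaged map in [0, 1].
#' @export
average_window <- function(maps) {
  maps <- as.matrix(maps)
  stopifnot(nrow(maps) >= 1)
  colMeans(maps)
}

#' Centroid of a set of grid points
#'
#' Arithmetic mean of latitudes and of longitudes (plane-surface
#' assumption).
#'
#' @param lat,lon Coordinates of the points, decimal degrees.
#' @return Named vector `c(lat, lon)`.
#' @export
centroid <- function(lat, lon) {
  stopifnot(length(lat) == length(lon), length(lat) >= 1)
  c(lat = mean(lat), lon = mean(lon))
}

#' Positional standard deviation of a set of grid points
#'
#' Population standard deviation (divisor n) of the latitudes and of the
#' longitudes — the cluster-density measure attached to a centroid.
#'
#' @inheritParams centroid
#' @return Named vector `c(lat, lon)`.
#' @export
positional_std <- function(lat, lon) {
  stopifnot(length(lat) == length(lon), length(lat) >= 1)
  n <- length(lat)
  c(lat = sqrt(sum((lat - mean(lat))^2) / n),
    lon = sqrt(sum((lon - mean(lon))^2) / n))
}

#' Cluster radius from centroid and positional standard deviation
#'
#' The Haversine distance between the centroid C and the point displaced by
#' the positional standard deviation, C + s — a single length (km) for the
#' spreading of the cluster around its centre.
#'
#' @param C Centroid `c(lat, lon)` in degrees.
#' @param s Positional standard deviation `c(lat, lon)` in degrees.
#' @return Radius in km.
#' @export
cluster_radius <- function(C, s) {
  stopifnot(all(is.finite(C)), all(is.finite(s)))
  haversine_km(C[[1]], C[[2]], C[[1]] + s[[1]], C[[2]] + s[[2]])
}

#' Points selected repeatedly within a window
#'
#' Grid points classified as anomalous on at least two days of the window
#' are flagged as persistent.
#'
#' @param selections List of per-day selected-index vectors.
#' @return Integer vector of persistent point indices.
#' @export
persistence_flags <- function(selections) {
  stopifnot(length(selections) >= 1)
  counts <- table(unlist(selections))
  as.integer(names(counts)[counts >= 2])
}

#' Evaluate a score field into per-window anomaly clusters
#'
#' The full evaluation chain: per-day top-fraction selection (std-scaled)
#' and 0-1 normalisation; segmentation of the period into windows of
#' similar wind direction; per-window averaging of the daily maps; then,
#' over the points with positive averaged value, the cluster centroid, the
#' positional standard deviation, the Haversine radius and the persistence
#' flags.
#'
#' @param field An `anomaly_score_field`.
#' @param grid The `grid_definition` the field's points refer to.
#' @param wind_direction Daily wind-direction series (degrees), same number
#'   of days as the field.
#' @param wind_speed Optional daily wind-speed series (m/s) carried into
#'   the window summaries.
#' @param cfg A `selection_config`.
#' @param angle_threshold Window-break threshold in degrees.
#' @return An `anomaly_evaluation`: list with `windows` (data frame:
#'   window span, mean direction/speed, centroid, std, radius, point
#'   count), `maps` (list of per-window averaged maps), and
#'   `persistent` (list of per-window persistent point indices).
#' @export
evaluate_anomalies <- function(field, grid, wind_direction,
                               wind_speed = NULL,
                               cfg = selection_config(),
                               angle_threshold = 45) {
  stopifnot(inherits(field, "anomaly_score_field"),
            inherits(grid, "grid_definition"),
            field$n_points == grid$n_points)
  if (length(wind_direction) != field$n_days)
    stop("evaluate_anomalies: wind series must cover the field's days")
  daily_std <- apply(field$scores, 1, stats::sd)
  month_mean_std <- mean(daily_std)
  sel <- lapply(seq_len(field$n_days), function(d)
    select_top(field$scores[d, ], cfg, daily_std[d], month_mean_std))
  maps <- do.call(rbind, lapply(sel, `[[`, "map"))
  win <- segment_windows(wind_direction, angle_threshold)

  out_maps <- vector("list", nrow(win))
  out_pers <- vector("list", nrow(win))
  rows <- lapply(seq_len(nrow(win)), function(i) {
    days <- win$start_day[i]:win$end_day[i]
    avg <- average_window(maps[days, , drop = FALSE])
    out_maps[[i]] <<- avg
    out_pers[[i]] <<- persistence_flags(lapply(sel[days], `[[`, "selected"))
    pos <- which(avg > 0)
    C <- centroid(grid$lat[pos], grid$lon[pos])
    s <- positional_std(grid$lat[pos], grid$lon[pos])
    data.frame(
      start_day = win$start_day[i], end_day = win$end_day[i],
      mean_direction = win$mean_direction[i],
      mean_speed = if (is.null(wind_speed)) NA_real_
                   else mean(wind_speed[days]),
      centroid_lat = C[["lat"]], centroid_lon = C[["lon"]],
      std_lat = s[["lat"]], std_lon = s[["lon"]],
      radius_km = cluster_radius(C, s),
      n_points = length(pos),
      n_persistent = length(out_pers[[i]]))
  })
  structure(list(windows = do.call(rbind, rows),
                 maps = out_maps,
                 persistent = out_pers,
                 daily_maps = maps,
                 config = cfg),
            class = "anomaly_evaluation")
}

#' @export
print.anomaly_evaluation <- function(x, ...) {
  cat(sprintf("<anomaly_evaluation> %d windows\n", nrow(x$windows)))
  print(x$windows, row.names = FALSE)
  invisible(x)
}
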