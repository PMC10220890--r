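# Independent oracles and shared fixtures. The oracles deliberately use
# different computational routes than the package internals.

# Spherical law of cosines on R = 6371 km.
slc_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371 * acos(pmin(pmax(d, -1), 1))
}

# Full-matrix DTW dynamic program (squared local cost, unit steps).
dtw_dp_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- (a[i] - b[j])^2 +
        min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  sqrt(D[n + 1, m + 1])
}

# Rank-based COPOD oracle: ECDFs via rank() with max/min ties, skewness
# via the moment formula on centred powers.
copod_rank_oracle <- function(X) {
  n <- nrow(X)
  nlog_l <- nlog_r <- matrix(0, n, ncol(X))
  skew <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    nlog_l[, j] <- -log(rank(x, ties.method = "max") / n)
    nlog_r[, j] <- -log((n + 1 - rank(x, ties.method = "min")) / n)
    s <- sd(x)
    skew[j] <- if (s > 0)
      n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3) else 0
  }
  nlog_s <- nlog_l
  nlog_s[, skew >= 0] <- nlog_r[, skew >= 0]
  pmax(rowSums(nlog_l), rowSums(nlog_r), rowSums(nlog_s))
}

# A small registered-feature cube built directly from arrays, on a
# single-row west-east grid with one point per cube column.
make_cube <- function(values, lat_min = 55, lon_min = 7, spacing = 0.01) {
  np <- dim(values)[2]
  g <- build_grid(lat_min, lat_min + spacing / 2, lon_min,
                  lon_min + (np - 1) * spacing + spacing / 2, spacing)
  stopifnot(g$n_points == np)
  fused_cube(values, g)
}

# Random complete cube: n days x np points x given features.
random_cube <- function(n_days, np, feats = c("SST", "T0"), seed = 1) {
  set.seed(seed)
  vals <- array(rnorm(n_days * np * length(feats)),
                dim = c(n_days, np, length(feats)),
                dimnames = list(NULL, NULL, feats))
  make_cube(vals)
}

# The scaled study-like scenario used for end-to-end recovery tests:
# ~300-point grid, 31 days, cloud gaps, episodic wind-gated wake plume.
recovery_config <- function(seed, plume = TRUE,
                            magnitudes = c(SST = 4, T0 = 4,
                                           S0 = 4, TSM = 4),
                            wind_regimes = default_wind_regimes()) {
  scenario_config(
    lat_min = 55.0, lat_max = 55.2, lon_min = 6.9, lon_max = 7.2,
    spacing = 0.015, n_days = 31,
    wind_regimes = wind_regimes,
    plume = list(enabled = plume, magnitudes = magnitudes,
                 radius_km = 4, offset_km = 5, wind_gate = 9.5),
    seed = seed)
}

# Run the pipeline stages in memory for a scenario config.
run_stages <- function(cfg) {
  scn <- generate_scenario(cfg)
  cube <- fuse_scenario(scn)
  filled <- impute_cube(cube)
  field <- detect_temporal(filled)
  wind <- scenario_daily_wind(scn)
  ev <- evaluate_anomalies(field, scn$grid, wind$direction, wind$speed)
  list(scn = scn, cube = cube, filled = filled, field = field,
       wind = wind, ev = ev)
}

# Window with the most active plume days (ties -> earliest), and the mean
# plume centre over those active days.
active_window_target <- function(windows, plume_truth) {
  nact <- vapply(seq_len(nrow(windows)), function(i)
    sum(plume_truth$centers$active[
      windows$start_day[i]:windows$end_day[i]]), integer(1))
  i <- which.max(nact)
  days <- windows$start_day[i]:windows$end_day[i]
  act <- days[plume_truth$centers$active[days]]
  list(window = i,
       lat = mean(plume_truth$centers$lat[act]),
       lon = mean(plume_truth$centers$lon[act]))
}

# Compass bearing (deg clockwise from north) from point 1 to point 2 on
# the local tangent plane.
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  (atan2((lon2 - lon1) * cos(lat1 * pi / 180), lat2 - lat1) *
     180 / pi) %% 360
}
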