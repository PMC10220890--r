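# The scenario generator: determinism, field statistics, clouds, plume
# geometry, round trips.

test_that("identical seeds give identical scenarios", {
  cfg <- recovery_config(77)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(s1$sources, s2$sources)
  expect_identical(s1$truth, s2$truth)
})

test_that("temporal persistence controls day-to-day field correlation", {
  set.seed(51)
  f0 <- gaussian_field(50, 50, 1)
  indep <- gaussian_field(50, 50, 1, prev = f0, rho = 0)
  expect_lt(abs(cor(as.numeric(f0), as.numeric(indep))), 0.2)
  pers <- gaussian_field(50, 50, 1, prev = f0, rho = 0.9)
  expect_gt(cor(as.numeric(f0), as.numeric(pers)), 0.6)
})

test_that("the plume displaces downwind and shifts means inside the disc", {
  cfg <- recovery_config(52)
  scn <- generate_scenario(cfg)
  tr <- scn$truth
  fc <- tr$farm_centroid
  for (d in c(1, 10, 25)) {
    expected <- windwake:::displace_km(
      fc[["lat"]], fc[["lon"]],
      tr$regimes_by_day$direction[d] + 180, cfg$plume$offset_km)
    expect_equal(tr$plume$centers$lat[d], expected[["lat"]])
    expect_equal(tr$plume$centers$lon[d], expected[["lon"]])
    expect_equal(haversine_km(fc[["lat"]], fc[["lon"]],
                              tr$plume$centers$lat[d],
                              tr$plume$centers$lon[d]),
                 cfg$plume$offset_km, tolerance = 0.01)
  }
  # core perturbation magnitude visible in the raw model source (T0)
  t0src <- Filter(function(s) s$feature == "T0", scn$sources)[[1]]
  act <- which(tr$plume$centers$active)[1]
  day_rows <- t0src$data[windwake:::day_of_time(t0src$data$time) == act, ]
  d_km <- haversine_km(day_rows$lat, day_rows$lon,
                       tr$plume$centers$lat[act], tr$plume$centers$lon[act])
  lift <- mean(day_rows$value[d_km <= 2.4]) -
    mean(day_rows$value[d_km > 4])
  sd_t0 <- cfg$features$sd[cfg$features$feature == "T0"]
  expect_gt(lift, 4 * sd_t0 * 0.6)
  expect_lt(lift, 4 * sd_t0 * 1.4)
})

test_that("magnitude zero and disabled plumes leave fields unchanged", {
  obs <- data.frame(lat = runif(20, 55, 55.1), lon = runif(20, 7, 7.1),
                    value = rnorm(20))
  expect_identical(inject_plume(obs, c(55.05, 7.05), 3, 0), obs)
  cfg_off <- recovery_config(53, plume = FALSE)
  cfg_on0 <- recovery_config(53, magnitudes = c(SST = 0, T0 = 0,
                                                S0 = 0, TSM = 0))
  expect_identical(generate_scenario(cfg_off)$sources,
                   generate_scenario(cfg_on0)$sources)
})

test_that("cloud masks are shared across the satellite features", {
  cfg <- recovery_config(54, plume = FALSE)
  scn <- generate_scenario(cfg)
  cube <- fuse_scenario(scn)
  expect_identical(cube$mask[, , "SST"], cube$mask[, , "CHL"])
  expect_identical(cube$mask[, , "SST"], cube$mask[, , "TSM"])
  # model and wind features never masked
  for (f in c("u", "v", "T0", "S0", "wind_speed", "wind_direction"))
    expect_false(any(cube$mask[, , f]))
  # blob probability 0 -> no masking
  cfg0 <- recovery_config(55, plume = FALSE)
  cfg0$cloud$day_prob <- 0
  expect_false(any(fuse_scenario(generate_scenario(cfg0))$mask))
})

test_that("inject_clouds masks exactly the disc footprint", {
  obs <- data.frame(lat = rep(seq(55, 55.1, 0.01), 2),
                    lon = rep(c(7, 7.05), each = 11), value = 1)
  discs <- data.frame(lat = 55.05, lon = 7, radius_km = 2)
  masked <- inject_clouds(obs, discs)
  d <- haversine_km(obs$lat, obs$lon, 55.05, 7)
  expect_identical(is.na(masked$value), d <= 2)
  expect_identical(inject_clouds(obs, discs[0, ]), obs)
})

test_that("scenario files round-trip into the fusion stage", {
  cfg <- recovery_config(56, plume = FALSE)
  cfg$n_days <- 6
  cfg$wind_regimes <- data.frame(direction = c(270, 100),
                                 speed = c(8, 11), duration = c(3, 3))
  scn <- generate_scenario(cfg)
  dir <- file.path(tempdir(), "scn_roundtrip")
  write_scenario(scn, dir)
  src <- read_sources(dir)
  expect_setequal(vapply(src, function(s) s$feature, character(1)),
                  vapply(scn$sources, function(s) s$feature, character(1)))
  cube1 <- fuse(src, scn$grid, cfg$n_days)
  cube2 <- fuse_scenario(scn)
  for (f in cube2$features)   # file order may differ from source order
    expect_equal(cube1$values[, , f], cube2$values[, , f],
                 tolerance = 1e-9)
  farm <- read_farm_json(file.path(dir, "farm.json"))
  expect_equal(farm, scn$farm, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("wind-window segmentation recovers the regime boundaries", {
  ok <- 0
  for (seed in 1:10) {
    cfg <- recovery_config(400 + seed, plume = FALSE)
    scn <- generate_scenario(cfg)
    wind <- scenario_daily_wind(scn)
    w <- segment_windows(wind$direction)
    truth_breaks <- cumsum(cfg$wind_regimes$duration)
    truth_breaks <- truth_breaks[-length(truth_breaks)]
    found <- w$end_day[-nrow(w)]
    hit <- all(vapply(truth_breaks, function(b)
      any(abs(found - b) <= 1), logical(1)))
    ok <- ok + hit
  }
  expect_gte(ok, 8)
})

test_that("regime durations must sum to the day count", {
  expect_error(scenario_config(n_days = 30), "sum to n_days")
})
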