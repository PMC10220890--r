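test_that("haversine distance matches the spherical-law-of-cosines oracle", {
  expect_identical(haversine_km(55, 7, 55, 7), 0)
  # one grid step north of the FINO3 platform; the law-of-cosines oracle
  # is ill-conditioned at short range, so agreement is sub-millimetre
  expect_lt(abs(haversine_km(55.195, 7.158, 55.199, 7.158) -
                  slc_km(55.195, 7.158, 55.199, 7.158)), 1e-6)
  # half great circle
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  set.seed(1)
  for (i in 1:20) {
    p <- runif(4, c(54, 6, 54, 6), c(56, 8, 56, 8))
    expect_lt(abs(haversine_km(p[1], p[2], p[3], p[4]) -
                    slc_km(p[1], p[2], p[3], p[4])), 1e-6)
  }
  expect_error(haversine_km(NA, 7, 55, 7), "finite")
  expect_error(haversine_km(95, 7, 55, 7), "latitudes")
})

test_that("haversine behaves as a metric on random triples", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(2, c(50, 0), c(60, 15)); b <- runif(2, c(50, 0), c(60, 15))
    c_ <- runif(2, c(50, 0), c(60, 15))
    dab <- haversine_km(a[1], a[2], b[1], b[2])
    dba <- haversine_km(b[1], b[2], a[1], a[2])
    expect_equal(dab, dba)
    expect_gte(haversine_km(a[1], a[2], c_[1], c_[2]) +
                 haversine_km(c_[1], c_[2], b[1], b[2]), dab - 1e-9)
  }
})

test_that("build_grid reproduces the study grid and small enumerations", {
  g <- build_grid(54.97, 55.32, 6.92, 7.47, 0.004)
  expect_equal(g$n_lat, 88)
  expect_equal(g$n_lon, 138)
  expect_equal(g$n_points, 12144)
  expect_equal(build_grid(0, 0.004, 0, 0.004, 0.004)$n_points, 4)
  expect_equal(build_grid(0, 0.01, 0, 0.01, 0.004)$n_points, 9)
  expect_error(build_grid(1, 0, 0, 1, 0.1), "ordered")
  expect_error(build_grid(0, 1, 0, 1, -1))
})

test_that("build_grid point count equals explicit enumeration on random bounds", {
  set.seed(7)
  for (i in 1:100) {
    lo <- runif(2, 0, 10)
    span <- runif(2, 0.01, 2)
    sp <- runif(1, 0.003, 0.5)
    g <- build_grid(lo[1], lo[1] + span[1], lo[2], lo[2] + span[2], sp)
    n_lat <- sum(lo[1] + (0:1e4) * sp <= lo[1] + span[1] + 1e-9)
    n_lon <- sum(lo[2] + (0:1e4) * sp <= lo[2] + span[2] + 1e-9)
    expect_equal(g$n_points, n_lat * n_lon)
    expect_equal(g$n_points, length(g$lat))
    expect_true(all(g$lat <= g$lat_max + 1e-9) &&
                  all(g$lon <= g$lon_max + 1e-9))
  }
})

test_that("grid indexing is row-major from the south-west corner", {
  g <- build_grid(0, 0.01, 0, 0.01, 0.005)  # 3 x 3
  expect_equal(g$lat[1:3], c(0, 0, 0))
  expect_equal(g$lon[1:3], c(0, 0.005, 0.01))
  expect_equal(g$lat[4], 0.005)
})

test_that("nearest-neighbour resampling adopts within 1 km and masks beyond", {
  g <- build_grid(55, 55.02, 7, 7.02, 0.01)  # 3 x 3, ~1.1 km lat steps
  # one observation exactly on the centre point
  obs <- data.frame(lat = 55.01, lon = 7.01, value = 3.5)
  v <- resample_nearest(obs, g)
  centre <- which(g$lat == 55.01 & g$lon == 7.01)
  expect_equal(v[centre], 3.5)
  d <- haversine_km(g$lat, g$lon, 55.01, 7.01)
  expect_true(all(is.na(v[d > 1])))
  expect_true(all(v[d <= 1] == 3.5, na.rm = FALSE))
  # everything farther than the cutoff -> fully masked
  far <- data.frame(lat = 55.5, lon = 7.5, value = 1)
  expect_true(all(is.na(resample_nearest(far, g))))
  # empty observations -> fully masked, not an error
  expect_true(all(is.na(resample_nearest(obs[0, ], g))))
})

test_that("equidistant observations resolve to the lower index", {
  g <- build_grid(55, 55.001, 7, 7.001, 0.01)  # single point
  obs <- data.frame(lat = c(55.002, 54.998), lon = c(7, 7),
                    value = c(10, 20))
  expect_equal(resample_nearest(obs, g), 10)
  # swapped order flips the winner
  expect_equal(resample_nearest(obs[2:1, ], g), 20)
})

test_that("resampling is idempotent for observations sitting on the grid", {
  g <- build_grid(55, 55.02, 7, 7.02, 0.01)
  obs <- data.frame(lat = g$lat, lon = g$lon, value = seq_len(g$n_points))
  v1 <- resample_nearest(obs, g)
  expect_equal(v1, as.numeric(seq_len(g$n_points)))
  v2 <- resample_nearest(data.frame(lat = g$lat, lon = g$lon, value = v1), g)
  expect_equal(v2, v1)
})

test_that("point sources broadcast to every grid point", {
  g <- build_grid(0, 0.01, 0, 0.01, 0.01)  # 4 points
  expect_equal(broadcast_point_source(8.3, g), rep(8.3, 4))
  expect_true(all(is.na(broadcast_point_source(NaN, g))))
  g2 <- build_grid(0, 0.05, 0, 0.05, 0.01)
  expect_length(broadcast_point_source(1, g2), g2$n_points)
})

test_that("overpass alignment averages within the window", {
  w <- matrix(c(0, 100), 1)
  expect_equal(align_to_overpass(c(10, 50, 90), c(5, 5, 5), w), 5)
  expect_equal(align_to_overpass(c(10, 50, 90), c(2, 4, 6), w), 4)
  # circular mean across the north wrap
  expect_equal(align_to_overpass(c(10, 50), c(350, 10), w, circular = TRUE),
               0, tolerance = 1e-9)
  # vector-sum oracle on random direction sets
  set.seed(3)
  for (i in 1:20) {
    d <- runif(5, 0, 360)
    expected <- (atan2(mean(sin(d * pi / 180)), mean(cos(d * pi / 180))) *
                   180 / pi) %% 360
    expect_equal(align_to_overpass(1:5, d, matrix(c(0, 10), 1),
                                   circular = TRUE), expected)
  }
  # day with no samples in the window is missing
  expect_true(is.na(align_to_overpass(c(10, 20), c(1, 2),
                                      matrix(c(50, 60), 1))))
  expect_error(align_to_overpass(c(5, 1), c(1, 2), w), "sorted")
})

test_that("the study bounding box exceeds 1300 square kilometres", {
  expect_gt(bbox_area_km2(54.97, 55.32, 6.92, 7.47), 1300)
  # small box vs planar approximation
  a <- bbox_area_km2(55, 55.01, 7, 7.01)
  planar <- (0.01 * pi / 180 * 6371)^2 * cos(55.005 * pi / 180)
  expect_equal(a, planar, tolerance = 1e-3)
})
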