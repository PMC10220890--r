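# Selection, wind-window segmentation, cluster geometry and persistence.

test_that("top-fraction selection counts and normalisation follow the rules", {
  set.seed(31)
  scores <- runif(100)
  cfg_off <- selection_config(scale_by_std = FALSE)
  s <- select_top(scores, cfg_off)
  expect_length(s$selected, 3)        # 3% of 100
  expect_setequal(s$selected, order(-scores)[1:3])
  expect_equal(range(s$map[s$selected]), c(0, 1))
  expect_true(all(s$map[-s$selected] == 0))
  # std scaling doubles the count
  s2 <- select_top(scores, selection_config(), daily_std = 2,
                   month_mean_std = 1)
  expect_length(s2$selected, 6)
  # constant scores: ties resolve by index, all normalised to 1
  # constant scores: ties resolve by index, all normalised to 1
  s3 <- select_top(rep(4, 50), cfg_off)
  expect_equal(s3$selected, c(1, 2))  # round(0.03 * 50) = 2, lowest indices
  expect_true(all(s3$map[s3$selected] == 1))
})

test_that("selected counts are clipped to [1, N] and respect overrides", {
  expect_length(select_top(runif(10), selection_config(),
                           daily_std = 100, month_mean_std = 1)$selected, 10)
  expect_length(select_top(runif(10), selection_config(),
                           daily_std = 1e-9, month_mean_std = 1)$selected, 1)
  s <- select_top(runif(200),
                  selection_config(farm_equivalent_points = 17,
                                   scale_by_std = FALSE))
  expect_length(s$selected, 17)
})

test_that("selection is monotone in scores", {
  set.seed(32)
  scores <- runif(60)
  cfg <- selection_config(scale_by_std = FALSE, base_fraction = 0.1)
  base <- select_top(scores, cfg)
  loser <- setdiff(seq_along(scores), base$selected)[1]
  scores2 <- scores
  scores2[loser] <- max(scores) + 1
  bumped <- select_top(scores2, cfg)
  expect_true(loser %in% bumped$selected)
  # the top scorer is never deselected by someone else's increase
  expect_true(which.max(scores) %in% bumped$selected)
})

test_that("wind windows segment greedily and partition the days", {
  one <- segment_windows(rep(120, 10))
  expect_equal(nrow(one), 1)
  expect_equal(one$end_day, 10)
  two <- segment_windows(c(rep(270, 5), rep(90, 5)))
  expect_equal(two$start_day, c(1, 6))
  expect_equal(two$end_day, c(5, 10))
  # sub-threshold alternation stays one window
  wiggle <- segment_windows(rep(c(100, 110), 8))
  expect_equal(nrow(wiggle), 1)
  expect_error(segment_windows(numeric(0)), "empty")
  # partition property on random series, including across the north wrap
  set.seed(33)
  for (i in 1:20) {
    dirs <- (cumsum(rnorm(25, 0, 40))) %% 360
    w <- segment_windows(dirs)
    expect_equal(w$start_day[1], 1)
    expect_equal(w$end_day[nrow(w)], 25)
    if (nrow(w) > 1)
      expect_equal(w$start_day[-1], w$end_day[-nrow(w)] + 1)
  }
})

test_that("window averaging is the per-point mean with zeros counted", {
  m <- rbind(c(1, 0, 0.5), c(0, 0, 0.5))
  expect_equal(average_window(m), c(0.5, 0, 0.5))
  expect_equal(average_window(m[1, , drop = FALSE]), m[1, ])
  sel <- matrix(0, 10, 4); sel[1:5, 2] <- 1
  expect_equal(average_window(sel)[2], 0.5)
})

test_that("centroid and positional standard deviation match their oracles", {
  expect_equal(centroid(55, 7), c(lat = 55, lon = 7))
  expect_equal(centroid(c(55, 55.2), c(7, 7.4)), c(lat = 55.1, lon = 7.2))
  expect_equal(positional_std(55, 7), c(lat = 0, lon = 0))
  expect_equal(positional_std(c(55, 55.2), c(7, 7)), c(lat = 0.1, lon = 0))
  set.seed(34)
  lat <- runif(100, 54, 56); lon <- runif(100, 6, 8)
  expect_equal(centroid(lat, lon),
               c(lat = sum(lat) / 100, lon = sum(lon) / 100),
               tolerance = 1e-12)
  # population (divisor n) two-pass variance oracle
  expect_equal(positional_std(lat, lon),
               c(lat = sqrt(mean((lat - mean(lat))^2)),
                 lon = sqrt(mean((lon - mean(lon))^2))),
               tolerance = 1e-12)
})

test_that("cluster radius is the haversine length of the std offset", {
  expect_equal(cluster_radius(c(55.1, 7.2), c(0, 0)), 0)
  r <- cluster_radius(c(55.1, 7.2), c(0.1, 0))
  expect_equal(r, 0.1 * pi * 6371 / 180, tolerance = 1e-4)
  expect_equal(r, slc_km(55.1, 7.2, 55.2, 7.2), tolerance = 1e-7)
  # permutation invariance through the full geometry chain
  set.seed(35)
  lat <- runif(30, 54, 56); lon <- runif(30, 6, 8)
  p <- sample(30)
  expect_equal(cluster_radius(centroid(lat, lon),
                              positional_std(lat, lon)),
               cluster_radius(centroid(lat[p], lon[p]),
                              positional_std(lat[p], lon[p])))
})

test_that("persistence flags points selected at least twice", {
  expect_length(persistence_flags(list(c(1, 2, 3))), 0)
  expect_equal(persistence_flags(list(c(1, 2), c(5), c(2, 7))), 2)
  sel <- list(c(1, 2, 3), c(3, 4), c(1, 3))
  flags <- persistence_flags(sel)
  expect_true(all(flags %in% unique(unlist(sel))))
})

test_that("evaluation recovers a stationary high-score blob", {
  set.seed(36)
  g <- build_grid(55, 55.001, 7, 8.2, 0.01)   # 121 points in a row
  scores <- matrix(runif(12 * 121), 12, 121)
  blob <- 28:32
  scores[, blob] <- scores[, blob] + 10       # persistently anomalous
  f <- anomaly_score_field(scores, "temporal", "copod", c("SST", "T0"))
  ev <- evaluate_anomalies(f, g, rep(200, 12))
  expect_equal(nrow(ev$windows), 1)
  C <- c(ev$windows$centroid_lat, ev$windows$centroid_lon)
  expect_lt(min(haversine_km(C[1], C[2], g$lat[blob], g$lon[blob])), 2)
  expect_true(all(ev$persistent[[1]] %in% blob))
  expect_gt(length(ev$persistent[[1]]), 0)
  # uniform scores: selection is index-driven, count bookkeeping consistent
  fu <- anomaly_score_field(matrix(1, 5, 121), "temporal", "copod",
                            c("SST", "T0"))
  evu <- evaluate_anomalies(fu, g, rep(90, 5))
  expect_equal(evu$windows$n_points, length(which(evu$maps[[1]] > 0)))
})

test_that("evaluation validates day alignment", {
  f <- anomaly_score_field(matrix(runif(20), 4, 5), "temporal", "copod",
                           "SST")
  g <- build_grid(55, 55.001, 7, 7.041, 0.01)  # 5 points
  expect_error(evaluate_anomalies(f, g, rep(1, 3)), "cover")
})
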