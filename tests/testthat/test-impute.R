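# DTW-kNN gap filling: gap detection, single-model and ensemble
# imputation, cube-wide behaviour.

test_that("find_gaps encodes maximal missing runs", {
  expect_equal(nrow(find_gaps(c(FALSE, FALSE))), 0)
  g <- find_gaps(c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(g$start, c(2, 5))
  expect_equal(g$end, c(3, 5))
  expect_equal(g$length, c(2, 1))
  g2 <- find_gaps(rep(TRUE, 4))
  expect_equal(g2, data.frame(start = 1L, end = 4L, length = 4L))
})

test_that("a gap in a constant series is filled with the constant", {
  mat <- matrix(5, 20, 1, dimnames = list(NULL, "SST"))
  mat[9, 1] <- NA
  g <- data.frame(start = 9, end = 9)
  expect_equal(impute_gap(mat, "SST", g), 5)
  expect_equal(impute_ensemble(mat, "SST", g), 5)
})

test_that("dtw-knn beats linear interpolation on a periodic series with a long gap", {
  t <- 1:64
  x <- sin(2 * pi * t / 8)
  mat <- matrix(x, ncol = 1, dimnames = list(NULL, "CHL"))
  mat[30:34, 1] <- NA
  g <- data.frame(start = 30, end = 34)
  truth <- x[30:34]
  rmse <- function(est) sqrt(mean((est - truth)^2))
  expect_lt(rmse(impute_gap(mat, "CHL", g)),
            rmse(windwake:::linear_fill(mat[, 1], 30:34)))
})

test_that("too few candidates falls back to linear interpolation", {
  set.seed(4)
  x <- rnorm(14)
  mat <- matrix(x, ncol = 1, dimnames = list(NULL, "SST"))
  mat[6:9, 1] <- NA
  g <- data.frame(start = 6, end = 9)
  # window length 3 + 4 + 3 = 10 on 14 days leaves < k candidates
  cfg <- dtwknn_config(w = 3, k = 3)
  expect_equal(impute_gap(mat, "SST", g, cfg),
               windwake:::linear_fill(mat[, 1], 6:9))
})

test_that("ensembles average their members position-wise", {
  set.seed(8)
  mat <- seasonal_multiseries(64)
  colnames(mat) <- c("CHL", "S0", "T0")
  mat[20:24, "CHL"] <- NA
  g <- data.frame(start = 20, end = 24)
  cfg1 <- dtwknn_config(w = 3, k = 3)
  cfg2 <- dtwknn_config(w = 5, k = 3)
  # identical members reproduce the single model
  expect_equal(impute_ensemble(mat, "CHL", g, list(cfg1, cfg1)),
               impute_gap(mat, "CHL", g, cfg1))
  # two members average exactly
  expect_equal(impute_ensemble(mat, "CHL", g, list(cfg1, cfg2)),
               (impute_gap(mat, "CHL", g, cfg1) +
                  impute_gap(mat, "CHL", g, cfg2)) / 2)
  expect_error(impute_ensemble(mat, "CHL", g, list()), "empty")
  expect_error(impute_gap(mat, "nope", g), "absent")
})

test_that("imputation is deterministic and never touches observed values", {
  cfg <- recovery_config(3, plume = FALSE)
  cfg$n_days <- 12
  cfg$wind_regimes <- data.frame(direction = 270, speed = 8, duration = 12)
  scn <- generate_scenario(cfg)
  cube <- fuse_scenario(scn)
  expect_gt(sum(cube$mask), 0)
  f1 <- impute_cube(cube)
  f2 <- impute_cube(cube)
  expect_false(any(f1$mask))
  expect_identical(f1$values, f2$values)
  expect_identical(f1$values[!cube$mask], cube$values[!cube$mask])
  # a gapless cube passes through unchanged
  f3 <- impute_cube(f1)
  expect_identical(f3$values, f1$values)
})

test_that("imputed satellite traces stay continuous with their neighbours", {
  cfg <- recovery_config(5, plume = FALSE)
  scn <- generate_scenario(cfg)
  cube <- fuse_scenario(scn)
  filled <- impute_cube(cube)
  for (f in c("TSM", "CHL")) {
    jumps <- abs(apply(filled$values[, , f], 2, diff))
    # day pairs with at least one imputed member
    imp_pair <- apply(cube$mask[, , f], 2,
                      function(m) m[-1] | m[-length(m)])
    obs_sd <- sd(apply(cube$values[, , f], 2, diff), na.rm = TRUE)
    expect_lt(max(jumps[imp_pair]), 5 * obs_sd)
  }
})

test_that("series with under two observations get mean-filled", {
  vals <- array(rnorm(10 * 4 * 2), c(10, 4, 2),
                dimnames = list(NULL, NULL, c("SST", "T0")))
  vals[2:10, 2, "SST"] <- NA   # one observation only
  cube <- make_cube(vals)
  filled <- impute_cube(cube)
  expect_false(any(filled$mask))
  expect_equal(attr(filled, "mean_filled"), 1L)
  fm <- mean(vals[, , "SST"][is.finite(vals[, , "SST"])])
  expect_equal(unname(filled$values[2, 2, "SST"]), fm)
})
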