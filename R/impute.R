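# Gap filling for per-grid-point multivariate time series: DTW-kNN window
# matching, single-model or ensemble, with a linear-interpolation fallback.

#' Configuration of a single DTW-kNN imputation model
#'
#' The model fills a gap by comparing the observed context around it (a
#' window of `w` days on each side) with every equally sized, fully
#' observed window elsewhere in the same series, ranking candidates by the
#' sum of per-feature DTW distances between the contexts, and averaging the
#' `k` nearest candidates' values at the gap-aligned positions.
#'
#' @param w Context radius: observed days used on each side of the gap.
#' @param k Number of nearest candidate windows averaged.
#' @param weighting `"uniform"` or `"inverse"` (inverse-distance weights).
#' @param dtw_band Sakoe--Chiba radius in days (default 2), or `NULL` for
#'   unconstrained warping.
#' @param z_normalize Standardise each feature by its whole observed
#'   series mean and standard deviation before computing distances, making
#'   the multivariate match scale-free across features while preserving
#'   window-level information.
#' @param distance `"dtw"` or `"euclidean"`; the latter is the plain-kNN
#'   baseline that ranks windows by raw Euclidean context distance.
#' @return A `dtwknn_config` list.
#' @export
dtwknn_config <- function(w = 3, k = 3, weighting = c("inverse", "uniform"),
                          dtw_band = 2, z_normalize = TRUE,
                          distance = c("dtw", "euclidean")) {
  stopifnot(w >= 1, k >= 1)
  structure(list(w = as.integer(w), k = as.integer(k),
                 weighting = match.arg(weighting),
                 dtw_band = dtw_band,
                 z_normalize = isTRUE(z_normalize),
                 distance = match.arg(distance)),
            class = "dtwknn_config")
}

#' Default DTW-kNN ensemble
#'
#' Three members with graded context radii (3, 4 and 5 days; k = 3,
#' inverse-distance weighting), sized to work on month-long (31-day)
#' series; member outputs are averaged position-wise.
#'
#' @return List of `dtwknn_config` members with class `dtwknn_ensemble`.
#' @export
default_ensemble <- function() {
  structure(list(dtwknn_config(w = 3, k = 3),
                 dtwknn_config(w = 4, k = 3),
                 dtwknn_config(w = 5, k = 3)),
            class = "dtwknn_ensemble")
}

#' Find maximal runs of missing values
#'
#' @param mask Logical vector, `TRUE` where the value is missing.
#' @return Data frame with one row per gap: `start`, `end` (1-based,
#'   inclusive) and `length`, ordered by `start`.
#' @export
find_gaps <- function(mask) {
  mask <- as.logical(mask)
  if (length(mask) == 0 || !any(mask))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

# Linear interpolation over the observed entries of a series, with constant
# extension beyond the first/last observation. Returns values at `at`.
linear_fill <- function(x, at) {
  obs <- which(is.finite(x))
  if (length(obs) == 0) return(rep(NA_real_, length(at)))
  if (length(obs) == 1) return(rep(x[obs], length(at)))
  stats::approx(obs, x[obs], xout = at, rule = 2)$y
}

#' Fill one gap in a multivariate series with a single DTW-kNN model
#'
#' The query is the multivariate context block of up to `w` observed days
#' on each side of the gap (one-sided at the series boundary), restricted
#' to features fully observed there. Candidates are all windows of length
#' `left + gap + right` that do not overlap the gap and are fully observed
#' in the target feature (and in the distance features at the
#' context-aligned positions). Candidate ranking uses the sum of
#' per-feature distances between the query context and the candidate's
#' context-aligned values; gap values are the weighted mean of the k
#' nearest candidates' target values at the gap-aligned positions. When
#' fewer than k candidates exist (or no usable context/feature), the gap
#' falls back to linear interpolation.
#'
#' @param mat Numeric day x feature matrix with `NA` for missing entries;
#'   columns named.
#' @param target Name of the feature whose gap is filled.
#' @param gap One row of [find_gaps()] output (fields `start`, `end`).
#' @param cfg A `dtwknn_config`.
#' @return Numeric vector of length `gap$end - gap$start + 1`.
#' @export
impute_gap <- function(mat, target, gap, cfg = dtwknn_config()) {
  stopifnot(inherits(cfg, "dtwknn_config"))
  if (!target %in% colnames(mat))
    stop(sprintf("impute_gap: feature '%s' absent from series", target))
  n <- nrow(mat)
  s <- gap$start; e <- gap$end
  L <- e - s + 1L
  gap_pos <- s:e

  left <- seq.int(max(1L, s - cfg$w), s - 1L)
  left <- left[left >= 1L]
  right <- seq.int(e + 1L, min(n, e + cfg$w))
  right <- right[right <= n]
  ctx <- c(left, right)
  fallback <- function() linear_fill(mat[, target], gap_pos)
  if (length(ctx) == 0) return(fallback())

  # distance features: fully observed over the query context
  feats <- colnames(mat)[colSums(!is.finite(mat[ctx, , drop = FALSE])) == 0]
  if (length(feats) == 0) return(fallback())

  nl <- length(left); nr <- length(right)
  len <- nl + L + nr
  if (len > n) return(fallback())
  starts <- seq_len(n - len + 1L)
  # windows must not overlap the gap itself
  starts <- starts[starts + len - 1L < s | starts > e]
  if (length(starts) < cfg$k) return(fallback())

  ctx_off <- c(seq_len(nl), nl + L + seq_len(nr))   # context positions
  mid_off <- nl + seq_len(L)                        # gap-aligned positions

  # per-feature standardisation over the whole observed series
  stats_of <- function(f) {
    v <- mat[, f][is.finite(mat[, f])]
    s <- stats::sd(v)
    c(mu = mean(v), sd = if (is.finite(s) && s > 0) s else 1)
  }
  fs <- if (cfg$z_normalize) vapply(feats, stats_of, numeric(2))
        else matrix(c(0, 1), 2, length(feats),
                    dimnames = list(c("mu", "sd"), feats))
  q <- vapply(feats, function(f)
    (mat[ctx, f] - fs["mu", f]) / fs["sd", f], numeric(length(ctx)))
  if (is.null(dim(q))) q <- matrix(q, nrow = length(ctx))

  band <- if (is.null(cfg$dtw_band)) -1L else as.integer(cfg$dtw_band)
  d <- gap_distances_cpp(mat, as.integer(starts), as.integer(ctx_off),
                         as.integer(mid_off),
                         match(feats, colnames(mat)),
                         match(target, colnames(mat)),
                         q, fs["mu", ], fs["sd", ], band,
                         cfg$distance == "euclidean")
  ok <- is.finite(d)
  if (sum(ok) < cfg$k) return(fallback())
  starts <- starts[ok]; d <- d[ok]
  sel <- order(d, starts)[seq_len(cfg$k)]
  wts <- if (cfg$weighting == "inverse") 1 / (d[sel] + 1e-12)
         else rep(1, cfg$k)
  wts <- wts / sum(wts)
  vals <- vapply(seq_len(cfg$k), function(i) {
    win <- starts[sel[i]]:(starts[sel[i]] + len - 1L)
    mat[win[mid_off], target]
  }, numeric(L))
  if (L == 1L) sum(vals * wts) else as.numeric(vals %*% wts)
}

#' Fill one gap with an ensemble of DTW-kNN models
#'
#' Position-wise arithmetic mean of the member outputs.
#'
#' @inheritParams impute_gap
#' @param ensemble List of `dtwknn_config` members (non-empty).
#' @return Numeric vector of gap values.
#' @export
impute_ensemble <- function(mat, target, gap, ensemble = default_ensemble()) {
  if (length(ensemble) == 0) stop("impute_ensemble: empty ensemble")
  outs <- lapply(ensemble, function(cfg) impute_gap(mat, target, gap, cfg))
  Reduce(`+`, outs) / length(outs)
}

#' Impute every gap in a fused cube
#'
#' Runs the DTW-kNN ensemble over each grid point's multivariate series,
#' feature by feature, gap by gap. Observed values are never altered. A
#' feature with fewer than two observed days at a point cannot support
#' window matching or interpolation and is filled with the feature's
#' cube-wide observed mean (counted in the returned log).
#'
#' @param cube A `fused_cube`.
#' @param ensemble List of `dtwknn_config` members.
#' @return A `fused_cube` with an empty mask; attribute `mean_filled` holds
#'   the number of point/feature series that required mean filling.
#' @export
impute_cube <- function(cube, ensemble = default_ensemble()) {
  stopifnot(inherits(cube, "fused_cube"))
  vals <- cube$values
  feats <- cube$features
  feat_means <- vapply(feats, function(f)
    mean(vals[, , f][is.finite(vals[, , f])]), numeric(1))
  mean_filled <- 0L
  for (p in seq_len(cube$grid$n_points)) {
    mat <- vals[, p, , drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(feats),
                                         dimnames = list(NULL, feats))
    if (all(is.finite(mat))) next
    for (f in feats) {
      col <- mat[, f]
      if (all(is.finite(col))) next
      if (sum(is.finite(col)) < 2) {
        fill <- feat_means[[f]]
        if (!is.finite(fill)) fill <- 0
        mat[!is.finite(col), f] <- fill
        mean_filled <- mean_filled + 1L
        next
      }
      gaps <- find_gaps(!is.finite(col))
      for (gi in seq_len(nrow(gaps))) {
        g <- gaps[gi, ]
        mat[g$start:g$end, f] <- impute_ensemble(mat, f, g, ensemble)
      }
    }
    vals[, p, ] <- mat
  }
  out <- fused_cube(vals, cube$grid)
  attr(out, "mean_filled") <- mean_filled
  out
}
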