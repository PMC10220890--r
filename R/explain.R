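# Dimensional outlier explanation for COPOD: per-feature score
# contributions, the 0.99 cutoff band, and corpus-level responsibility
# statistics.

#' Day of the maximum score in a series
#'
#' @param scores Per-day score vector (length >= 1).
#' @return Index of the maximum; ties resolve to the earliest day.
#' @export
argmax_day <- function(scores) {
  stopifnot(length(scores) >= 1)
  which.max(scores)
}

#' Per-feature contributions to a COPOD score
#'
#' Decomposes each sample's COPOD score into per-feature terms: the
#' \eqn{-\log} tail probabilities of the branch (left, right or
#' skewness-corrected) that attains the sample's maximum, so the
#' contributions sum exactly to the total score.
#'
#' @param model A `copod_model`.
#' @param X Matrix of samples to decompose (the fitted matrix in normal
#'   use).
#' @return samples x features matrix of non-negative contributions, with
#'   the per-sample total score as attribute `score`.
#' @export
dimensional_contributions <- function(model, X) {
  t <- copod_tails(model, X)
  out <- t$neglog_left
  out[t$branch == 2, ] <- t$neglog_right[t$branch == 2, , drop = FALSE]
  out[t$branch == 3, ] <- t$neglog_skew[t$branch == 3, , drop = FALSE]
  colnames(out) <- model$features
  attr(out, "score") <- t$score
  out
}

#' Per-feature cutoff band of dimensional contributions
#'
#' For each feature, the empirical `q`-quantile of that feature's
#' contributions across all samples of the fitted matrix; a sample's
#' feature is deemed responsible for its anomaly score when its
#' contribution exceeds the band.
#'
#' @param contributions samples x features contribution matrix
#'   (from [dimensional_contributions()], >= 2 samples).
#' @param q Quantile level in the open interval (0, 1); default 0.99.
#' @return Named per-feature band values.
#' @export
cutoff_band <- function(contributions, q = 0.99) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1)
    stop("cutoff_band: q must lie strictly between 0 and 1")
  stopifnot(nrow(contributions) >= 2)
  apply(contributions, 2, stats::quantile, probs = q, names = FALSE)
}

#' Explain one grid point's strongest anomaly
#'
#' Fits COPOD on the point's days x features matrix, finds the day with
#' the highest anomaly score, and reports the features whose dimensional
#' contributions on that day reach the cutoff band. With short series the
#' largest possible contribution, \eqn{-\log(1/n)}, ties the 0.99 band
#' exactly, so reaching the band (rather than strictly exceeding it)
#' is the operative rule; a zero contribution is never responsible, so
#' constant features cannot be flagged.
#'
#' @param X The point's days x features matrix (complete).
#' @param q Cutoff band quantile (default 0.99).
#' @param day Day (row) to explain; by default the day with the highest
#'   anomaly score.
#' @return An `explanation` list: `day` (explained day index), `score`,
#'   `contributions` (per feature, that day), `band` (per feature),
#'   `responsible` (character vector of features reaching the band).
#' @export
explain_point <- function(X, q = 0.99, day = NULL) {
  model <- copod_fit(X)
  contrib <- dimensional_contributions(model, X)
  scores <- attr(contrib, "score")
  if (is.null(day)) day <- argmax_day(scores)
  stopifnot(day >= 1, day <= nrow(X))
  band <- cutoff_band(contrib, q)
  resp <- colnames(contrib)[contrib[day, ] >= band & contrib[day, ] > 0]
  structure(list(day = day, score = scores[day],
                 contributions = contrib[day, ], band = band,
                 responsible = resp),
            class = "explanation")
}

#' @export
print.explanation <- function(x, ...) {
  cat(sprintf("<explanation> day %d, score %.3f\n", x$day, x$score))
  cat("  responsible:", if (length(x$responsible))
    paste(x$responsible, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Corpus-level explanation statistics
#'
#' Explains every grid point's strongest anomaly and aggregates which
#' features — and which feature combinations — are responsible across the
#' grid. Points whose top day has no feature above the band are counted
#' under the `(none)` combination.
#'
#' @param cube A complete `fused_cube`.
#' @param features Feature subset to explain; `NULL` selects the default
#'   detection features present in the cube.
#' @param q Cutoff band quantile.
#' @return An `explanation_stats` list: `per_point` data frame (point,
#'   day, score, responsible combination), `feature_counts` (named counts
#'   of responsibility per feature), `combination_counts` (named counts per
#'   responsible-feature combination, summing to the number of points).
#' @export
explain_corpus <- function(cube, features = NULL, q = 0.99) {
  stopifnot(inherits(cube, "fused_cube"))
  check_complete(cube)
  feats <- detect_features(cube, features, include_wind = FALSE)
  n_pts <- cube$grid$n_points
  combo <- character(n_pts)
  day <- integer(n_pts)
  score <- numeric(n_pts)
  feat_counts <- stats::setNames(integer(length(feats)), feats)
  for (p in seq_len(n_pts)) {
    X <- cube$values[, p, feats, drop = FALSE]
    dim(X) <- c(cube$n_days, length(feats))
    colnames(X) <- feats
    ex <- explain_point(X, q)
    day[p] <- ex$day
    score[p] <- ex$score
    r <- sort(ex$responsible)
    combo[p] <- if (length(r)) paste(r, collapse = "+") else "(none)"
    feat_counts[r] <- feat_counts[r] + 1L
  }
  structure(list(
    per_point = data.frame(point = seq_len(n_pts), day = day,
                           score = score, combination = combo),
    feature_counts = feat_counts,
    combination_counts = sort(table(combo), decreasing = TRUE)),
    class = "explanation_stats")
}

#' @export
print.explanation_stats <- function(x, ...) {
  cat(sprintf("<explanation_stats> %d points\n", nrow(x$per_point)))
  cat("  feature responsibility:\n")
  print(x$feature_counts)
  cat("  top combinations:\n")
  print(utils::head(x$combination_counts, 8))
  invisible(x)
}
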