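# Copula-based outlier detection: empirical tail probabilities per feature,
# combined as negative log sums with a skewness correction. Parameter-free
# and fully deterministic.

#' Fit a COPOD model
#'
#' Stores, per feature, the sorted sample values backing the left empirical
#' CDF \eqn{F(x) = \#\{x_i \le x\}/n}, the right empirical CDF
#' \eqn{G(x) = \#\{x_i \ge x\}/n}, and the adjusted Fisher--Pearson sample
#' skewness used to pick the tail per feature in the skewness-corrected
#' score term. Scoring is transductive: the model is meant to score the
#' matrix it was fitted on.
#'
#' @param X Numeric samples x features matrix, no missing entries,
#'   at least 2 rows.
#' @return A `copod_model`.
#' @export
copod_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("copod_fit: need at least 2 samples")
  if (any(!is.finite(X))) stop("copod_fit: matrix must be finite")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  structure(list(
    sorted = lapply(seq_len(ncol(X)), function(j) sort(X[, j])),
    skew = apply(X, 2, sample_skewness),
    n = nrow(X),
    features = colnames(X)
  ), class = "copod_model")
}

# Adjusted Fisher-Pearson skewness; 0 for degenerate samples.
sample_skewness <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 3 || !is.finite(s) || s == 0) return(0)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

# Left/right empirical tail probabilities for a sample vector against the
# model's sorted values: F = #{<= x}/n, G = #{>= x}/n (both >= 1/n on the
# fitted matrix).
ecdf_left <- function(sorted, x, n) findInterval(x, sorted) / n
ecdf_right <- function(sorted, x, n)
  (n - findInterval(x, sorted, left.open = TRUE)) / n

#' COPOD anomaly scores
#'
#' For sample \eqn{i} the three tail-probability aggregates are
#' \eqn{p_L = \sum_d -\log F_d(x_{id})}, \eqn{p_R = \sum_d -\log G_d(x_{id})}
#' and the skewness-corrected
#' \eqn{p_S = \sum_d -\log t_d(x_{id})} with \eqn{t_d = F_d} when the
#' feature's skewness is negative and \eqn{G_d} otherwise; the score is
#' \eqn{\max(p_L, p_R, p_S)}. Higher means more anomalous. A constant
#' feature has degenerate CDFs equal to 1 and contributes 0.
#'
#' @param model A `copod_model`.
#' @param X Matrix with the model's features (the fitted matrix in normal,
#'   transductive use).
#' @return Numeric vector of non-negative per-sample scores.
#' @export
copod_score <- function(model, X) {
  copod_tails(model, X)$score
}

# Shared core: per-feature -log tail probabilities for the three branches
# plus the winning branch per sample (needed by the explanation module).
copod_tails <- function(model, X) {
  stopifnot(inherits(model, "copod_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$features))
    stop("copod_score: feature mismatch")
  if (!is.null(colnames(X)) && !identical(colnames(X), model$features))
    stop("copod_score: feature mismatch")
  n <- model$n
  nl <- matrix(0, nrow(X), ncol(X))  # -log F
  nr <- matrix(0, nrow(X), ncol(X))  # -log G
  for (j in seq_len(ncol(X))) {
    f <- ecdf_left(model$sorted[[j]], X[, j], n)
    g <- ecdf_right(model$sorted[[j]], X[, j], n)
    # clamp: a value outside the fitted range has tail count 0; cap at 1/n
    nl[, j] <- -log(pmax(f, 1 / n))
    nr[, j] <- -log(pmax(g, 1 / n))
  }
  skew_right <- model$skew >= 0
  ns <- nl
  ns[, skew_right] <- nr[, skew_right]
  pl <- rowSums(nl); pr <- rowSums(nr); ps <- rowSums(ns)
  branch <- max.col(cbind(pl, pr, ps), ties.method = "first")
  list(neglog_left = nl, neglog_right = nr, neglog_skew = ns,
       p_left = pl, p_right = pr, p_skew = ps,
       branch = branch, score = pmax(pl, pr, ps))
}

#' @export
print.copod_model <- function(x, ...) {
  cat(sprintf("<copod_model> %d samples, %d features (%s)\n",
              x$n, length(x$features), paste(x$features, collapse = ", ")))
  invisible(x)
}
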