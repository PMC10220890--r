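# Dynamic time warping distance.

#' Dynamic-time-warping distance between two sequences
#'
#' Classic DTW with squared-difference local cost and unit steps
#' (match/insert/delete), optionally constrained to a Sakoe--Chiba band.
#' Returns the square root of the accumulated cost, so the distance of two
#' identical sequences is exactly 0 and, for equal-length sequences, DTW is
#' never larger than the Euclidean distance.
#'
#' @param a,b Non-empty finite numeric sequences.
#' @param band Sakoe--Chiba radius in samples, or `NULL` (default) for
#'   unconstrained warping. A band narrower than the length difference of
#'   the sequences admits no path and is widened to `abs(length(a) -
#'   length(b))`.
#' @return Non-negative scalar distance.
#' @examples
#' dtw_distance(c(0, 0, 1), c(0, 1))
#' @export
dtw_distance <- function(a, b, band = NULL) {
  if (length(a) == 0 || length(b) == 0)
    stop("dtw_distance: sequences must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("dtw_distance: sequences must be finite")
  b_int <- if (is.null(band)) -1L
           else max(as.integer(band), abs(length(a) - length(b)))
  sqrt(dtw_cost_cpp(as.numeric(a), as.numeric(b), b_int))
}
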