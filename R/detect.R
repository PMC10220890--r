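# Anomaly scoring over the fused cube: temporal mode (each grid point's
# series scored independently) and spatial mode (all grid points of one day
# scored jointly), with a pluggable detector registry. COPOD is the native
# default; external detectors (LOF, isolation forest, OCSVM, ...) can be
# registered as callables.

.detectors <- new.env(parent = emptyenv())

#' Register an anomaly detector
#'
#' A detector is a function mapping a samples x features matrix to one
#' non-negative-ish score per sample (higher = more anomalous). Registered
#' detectors are usable in both temporal and spatial mode. `"copod"` is
#' pre-registered.
#'
#' @param name Detector name; re-registering an existing name is an error
#'   unless `overwrite = TRUE`.
#' @param fit_score Function `(X) -> numeric(nrow(X))`.
#' @param overwrite Allow replacing an existing registration.
#' @return The name, invisibly.
#' @export
register_detector <- function(name, fit_score, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1, is.function(fit_score))
  if (!overwrite && !is.null(.detectors[[name]]))
    stop(sprintf("detector '%s' is already registered", name))
  assign(name, fit_score, envir = .detectors)
  invisible(name)
}

#' List registered detector names
#' @return Character vector.
#' @export
list_detectors <- function() sort(ls(.detectors))

get_detector <- function(name) {
  fn <- .detectors[[name]]
  if (is.null(fn))
    stop(sprintf("unknown detector '%s' (registered: %s)", name,
                 paste(list_detectors(), collapse = ", ")))
  fn
}

# Native default, registered on load.
copod_detector <- function(X) copod_score(copod_fit(X), X)

.onLoad <- function(libname, pkgname) {
  if (is.null(.detectors[["copod"]]))
    register_detector("copod", copod_detector)
}

# Default detection feature set: the seven satellite + model variables.
DEFAULT_DETECT_FEATURES <- c("SST", "CHL", "TSM", "u", "v", "T0", "S0")
WIND_FEATURES <- c("wind_speed", "wind_direction")

detect_features <- function(cube, features, include_wind) {
  if (is.null(features))
    features <- intersect(DEFAULT_DETECT_FEATURES, cube$features)
  miss <- setdiff(features, cube$features)
  if (length(miss))
    stop(sprintf("features not in cube: %s", paste(miss, collapse = ", ")))
  if (include_wind)
    features <- c(features, intersect(WIND_FEATURES, cube$features))
  features
}

check_complete <- function(cube) {
  if (any(cube$mask))
    stop("detection needs a complete (imputed) cube")
}

#' Temporal anomaly detection
#'
#' Scores each grid point's day-indexed multivariate series independently:
#' the detector is fitted on and applied to that point's days x features
#' matrix, so scores at a point depend only on that point's own history.
#'
#' @param cube A complete (fully imputed) `fused_cube` with at least 2 days.
#' @param detector Registered detector name (default `"copod"`).
#' @param include_wind Include the broadcast wind features as inputs
#'   (default `FALSE`, the configuration retained for evaluation).
#' @param features Feature subset to use; `NULL` selects the default seven
#'   satellite + model variables present in the cube.
#' @return An `anomaly_score_field` (day x point score matrix + metadata).
#' @export
detect_temporal <- function(cube, detector = "copod", include_wind = FALSE,
                            features = NULL) {
  stopifnot(inherits(cube, "fused_cube"))
  check_complete(cube)
  if (cube$n_days < 2) stop("detect_temporal: need at least 2 days")
  feats <- detect_features(cube, features, include_wind)
  fn <- get_detector(detector)
  scores <- matrix(NA_real_, cube$n_days, cube$grid$n_points)
  for (p in seq_len(cube$grid$n_points)) {
    X <- cube$values[, p, feats, drop = FALSE]
    dim(X) <- c(cube$n_days, length(feats))
    colnames(X) <- feats
    scores[, p] <- fn(X)
  }
  anomaly_score_field(scores, mode = "temporal", detector = detector,
                      features = feats, include_wind = include_wind)
}

#' Spatial anomaly detection for one day
#'
#' Scores all grid points of a single day jointly: the detector is fitted
#' on the points x features matrix of that day, without the time component.
#' Spatially constant features (broadcast wind) have degenerate empirical
#' CDFs and contribute nothing to COPOD scores, so including or excluding
#' the wind input leaves spatial COPOD scores unchanged.
#'
#' @param cube A complete `fused_cube`.
#' @param day Day index in `1..cube$n_days`.
#' @inheritParams detect_temporal
#' @return Numeric per-point score vector.
#' @export
detect_spatial <- function(cube, day, detector = "copod",
                           include_wind = FALSE, features = NULL) {
  stopifnot(inherits(cube, "fused_cube"))
  check_complete(cube)
  if (!(day %in% seq_len(cube$n_days)))
    stop(sprintf("detect_spatial: unknown day %s", day))
  feats <- detect_features(cube, features, include_wind)
  X <- cube$values[day, , feats, drop = FALSE]
  dim(X) <- c(cube$grid$n_points, length(feats))
  colnames(X) <- feats
  get_detector(detector)(X)
}

#' Run a detector over the cube in either mode
#'
#' Convenience wrapper producing a full day x point score field: temporal
#' mode scores each point's series; spatial mode scores each day's grid
#' separately (one detector fit per day).
#'
#' @inheritParams detect_temporal
#' @param mode `"temporal"` or `"spatial"`.
#' @return An `anomaly_score_field`.
#' @export
detect_anomalies <- function(cube, mode = c("temporal", "spatial"),
                             detector = "copod", include_wind = FALSE,
                             features = NULL) {
  mode <- match.arg(mode)
  if (mode == "temporal")
    return(detect_temporal(cube, detector, include_wind, features))
  feats <- detect_features(cube, features, include_wind)
  scores <- t(vapply(seq_len(cube$n_days), function(d)
    detect_spatial(cube, d, detector, include_wind, features),
    numeric(cube$grid$n_points)))
  anomaly_score_field(scores, mode = "spatial", detector = detector,
                      features = feats, include_wind = include_wind)
}

#' Construct an anomaly score field
#'
#' @param scores Finite day x point score matrix.
#' @param mode `"temporal"` or `"spatial"`.
#' @param detector Detector name.
#' @param features Features the detector saw.
#' @param include_wind Whether wind features were included.
#' @return An `anomaly_score_field`.
#' @export
anomaly_score_field <- function(scores, mode, detector, features,
                                include_wind = FALSE) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores)))
    stop("anomaly_score_field: scores must be finite")
  structure(list(scores = scores, mode = mode, detector = detector,
                 features = features, include_wind = include_wind,
                 n_days = nrow(scores), n_points = ncol(scores)),
            class = "anomaly_score_field")
}

#' @export
print.anomaly_score_field <- function(x, ...) {
  cat(sprintf("<anomaly_score_field> %s/%s: %d days x %d points\n",
              x$mode, x$detector, x$n_days, x$n_points))
  cat("  features:", paste(x$features, collapse = ", "),
      if (x$include_wind) "(incl. wind)" else "", "\n")
  invisible(x)
}
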