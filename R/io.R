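# Plain-text serialization: long-format CSV for cubes, score fields and
# source rasters (a '#'-prefixed JSON header line carries the metadata),
# GeoJSON-style polygons and JSON cluster/truth records.

write_csv_with_header <- function(df, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA)), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_csv_with_header <- function(path) {
  first <- readLines(path, n = 1)
  meta <- if (startsWith(first, "# "))
    jsonlite::fromJSON(sub("^# ", "", first)) else NULL
  df <- utils::read.csv(path, comment.char = "#")
  list(meta = meta, data = df)
}

#' Write / read a fused cube as long-format CSV
#'
#' Columns `day`, `point`, `feature`, `value` (empty = missing); the grid
#' definition travels in a JSON header comment so the cube round-trips
#' exactly.
#'
#' @param cube A `fused_cube`.
#' @param path Output/input file path.
#' @return `read_cube_csv` returns a `fused_cube`.
#' @export
write_cube_csv <- function(cube, path) {
  stopifnot(inherits(cube, "fused_cube"))
  g <- cube$grid
  idx <- expand.grid(day = seq_len(cube$n_days),
                     point = seq_len(g$n_points),
                     feature = cube$features,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx$value <- as.numeric(cube$values)
  meta <- list(kind = "fused_cube", lat_min = g$lat_min,
               lat_max = g$lat_max, lon_min = g$lon_min,
               lon_max = g$lon_max, spacing = g$spacing,
               n_days = cube$n_days, features = cube$features)
  write_csv_with_header(idx, meta, path)
  invisible(path)
}

#' @rdname write_cube_csv
#' @export
read_cube_csv <- function(path) {
  r <- read_csv_with_header(path)
  m <- r$meta
  if (is.null(m) || !identical(m$kind, "fused_cube"))
    stop("read_cube_csv: not a cube file")
  grid <- build_grid(m$lat_min, m$lat_max, m$lon_min, m$lon_max, m$spacing)
  feats <- m$features
  vals <- array(NA_real_, c(m$n_days, grid$n_points, length(feats)),
                dimnames = list(NULL, NULL, feats))
  d <- r$data
  vals[cbind(d$day, d$point, match(d$feature, feats))] <- d$value
  fused_cube(vals, grid)
}

#' Write / read an anomaly score field as CSV
#'
#' Columns `day`, `point`, `score`, with the detection metadata (mode,
#' detector, features, wind flag) in the JSON header. Reading requires the
#' matching grid only for downstream evaluation, not for the field itself.
#'
#' @param field An `anomaly_score_field`.
#' @param path File path.
#' @return `read_scores_csv` returns an `anomaly_score_field`.
#' @export
write_scores_csv <- function(field, path) {
  stopifnot(inherits(field, "anomaly_score_field"))
  idx <- expand.grid(day = seq_len(field$n_days),
                     point = seq_len(field$n_points),
                     KEEP.OUT.ATTRS = FALSE)
  idx$score <- as.numeric(field$scores)
  meta <- list(kind = "anomaly_scores", mode = field$mode,
               detector = field$detector, features = field$features,
               include_wind = field$include_wind,
               n_days = field$n_days, n_points = field$n_points)
  write_csv_with_header(idx, meta, path)
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(path) {
  r <- read_csv_with_header(path)
  m <- r$meta
  if (is.null(m) || !identical(m$kind, "anomaly_scores"))
    stop("read_scores_csv: not a score file")
  sc <- matrix(NA_real_, m$n_days, m$n_points)
  sc[cbind(r$data$day, r$data$point)] <- r$data$score
  anomaly_score_field(sc, m$mode, m$detector, m$features, m$include_wind)
}

#' Write a scenario's inputs to a directory of plain-text files
#'
#' Satellite and model sources become long-format raster CSVs (`time`,
#' `lat`, `lon`, `feature`, `value`), in-situ wind a point-series CSV
#' (`timestamp`, `feature`, `value`), the farm footprint a GeoJSON-style
#' polygon, and the ground truth a JSON file.
#'
#' @param scenario A `scenario`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in scenario$sources) {
    if (s$source_class == "in_situ") next
    df <- data.frame(time = s$data$time, lat = s$data$lat,
                     lon = s$data$lon, feature = s$feature,
                     value = s$data$value)
    write_csv_with_header(df, list(kind = "raster", feature = s$feature),
                          file.path(dir, paste0(s$feature, ".csv")))
  }
  wind <- do.call(rbind, lapply(scenario$sources, function(s) {
    if (s$source_class != "in_situ") return(NULL)
    data.frame(timestamp = s$data$time, feature = s$feature,
               value = s$data$value)
  }))
  utils::write.csv(wind, file.path(dir, "wind.csv"), row.names = FALSE)
  write_farm_json(scenario$farm, file.path(dir, "farm.json"))
  cfg <- scenario$config
  jsonlite::write_json(
    list(truth = scenario$truth,
         grid = list(lat_min = cfg$lat_min, lat_max = cfg$lat_max,
                     lon_min = cfg$lon_min, lon_max = cfg$lon_max,
                     spacing = cfg$spacing, n_days = cfg$n_days)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read scenario input files back into sources
#'
#' Counterpart of [write_scenario()]: reads every raster CSV and the wind
#' point-series CSV in `dir` into [ww_source()] objects.
#'
#' @param dir Directory written by [write_scenario()].
#' @return List of `ww_source`.
#' @export
read_sources <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  sources <- list()
  for (f in files) {
    if (basename(f) == "wind.csv") {
      w <- utils::read.csv(f)
      for (feat in unique(w$feature)) {
        rows <- w[w$feature == feat, ]
        sources <- c(sources, list(ww_source(
          feat, data.frame(time = rows$timestamp, value = rows$value))))
      }
    } else {
      r <- read_csv_with_header(f)
      if (is.null(r$meta) || !identical(r$meta$kind, "raster")) next
      sources <- c(sources, list(ww_source(
        r$meta$feature,
        data.frame(time = r$data$time, lat = r$data$lat,
                   lon = r$data$lon, value = r$data$value))))
    }
  }
  sources
}

#' Write / read a farm polygon as a GeoJSON-style file
#'
#' @param poly Data frame of vertices (`lat`, `lon`), closed ring.
#' @param path File path.
#' @return `read_farm_json` returns the polygon data frame.
#' @export
write_farm_json <- function(poly, path) {
  gj <- list(type = "Feature",
             properties = list(name = "farm"),
             geometry = list(type = "Polygon",
                             coordinates = list(
                               lapply(seq_len(nrow(poly)), function(i)
                                 c(poly$lon[i], poly$lat[i])))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_farm_json
#' @export
read_farm_json <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ring <- gj$geometry$coordinates[1, , ]
  data.frame(lat = ring[, 2], lon = ring[, 1])
}

#' Write evaluation results as JSON cluster records
#'
#' One record per time window: the day span, mean wind, centroid, the
#' positional standard deviation, the cluster radius, the selected-point
#' count and the persistent point indices.
#'
#' @param evaluation An `anomaly_evaluation`.
#' @param path File path.
#' @export
write_clusters_json <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "anomaly_evaluation"))
  w <- evaluation$windows
  records <- lapply(seq_len(nrow(w)), function(i) {
    list(start_day = w$start_day[i], end_day = w$end_day[i],
         mean_direction = w$mean_direction[i],
         mean_speed = w$mean_speed[i],
         centroid = c(lat = w$centroid_lat[i], lon = w$centroid_lon[i]),
         std = c(lat = w$std_lat[i], lon = w$std_lon[i]),
         radius_km = w$radius_km[i],
         n_points = w$n_points[i],
         persistent_points = evaluation$persistent[[i]])
  })
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
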