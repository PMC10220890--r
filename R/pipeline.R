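# End-to-end orchestration: simulate -> fuse -> impute -> detect ->
# evaluate -> explain, with serialized stage outputs and a checksum
# manifest for reproducibility.

#' Run configuration for the full pipeline
#'
#' @param scenario A `scenario_config` describing the synthetic inputs (or
#'   `NULL` when `sources_dir` points at existing input files).
#' @param sources_dir Directory of input files (from [write_scenario()])
#'   used instead of simulating.
#' @param detector Registered detector name.
#' @param mode `"temporal"` or `"spatial"`.
#' @param include_wind Give the detector the broadcast wind features.
#' @param selection A `selection_config`.
#' @param angle_threshold Wind-window break threshold, degrees.
#' @param ensemble Imputation ensemble (list of `dtwknn_config`).
#' @param explain_q Cutoff-band quantile for the explanation stage.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = scenario_config(), sources_dir = NULL,
                       detector = "copod", mode = "temporal",
                       include_wind = FALSE,
                       selection = selection_config(),
                       angle_threshold = 45,
                       ensemble = default_ensemble(),
                       explain_q = 0.99) {
  structure(list(scenario = scenario, sources_dir = sources_dir,
                 detector = detector, mode = mode,
                 include_wind = include_wind, selection = selection,
                 angle_threshold = angle_threshold, ensemble = ensemble,
                 explain_q = explain_q),
            class = "run_config")
}

#' Run the full monitoring pipeline
#'
#' Executes simulate, fuse, impute, detect, evaluate and explain in order,
#' writing each stage's output into `out_dir` and a manifest with per-file
#' MD5 checksums; a re-run with the identical configuration reproduces the
#' checksums bit for bit. Any stage failure aborts with the stage named.
#'
#' @param cfg A `run_config`.
#' @param out_dir Output directory (created).
#' @param render Also render per-window anomaly maps as PNG (cosmetic).
#' @return Invisibly, a list with the in-memory stage results
#'   (`scenario`, `cube`, `cube_filled`, `field`, `evaluation`, `stats`)
#'   and `manifest`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir, render = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  scenario <- stage("simulate", {
    if (!is.null(cfg$sources_dir)) {
      tr <- jsonlite::fromJSON(file.path(cfg$sources_dir, "truth.json"))
      g <- tr$grid
      list(sources = read_sources(cfg$sources_dir),
           grid = build_grid(g$lat_min, g$lat_max, g$lon_min, g$lon_max,
                             g$spacing),
           farm = read_farm_json(file.path(cfg$sources_dir, "farm.json")),
           truth = tr$truth,
           config = list(n_days = g$n_days, overpass_hour = 10))
    } else {
      s <- generate_scenario(cfg$scenario)
      write_scenario(s, file.path(out_dir, "sources"))
      s
    }
  })

  cube <- stage("fuse", {
    cb <- fuse(scenario$sources, scenario$grid, scenario$config$n_days,
               windows = overpass_windows(scenario$config$n_days,
                                          scenario$config$overpass_hour))
    write_cube_csv(cb, file.path(out_dir, "cube.csv"))
    cb
  })

  cube_filled <- stage("impute", {
    cf <- impute_cube(cube, cfg$ensemble)
    write_cube_csv(cf, file.path(out_dir, "cube_filled.csv"))
    cf
  })

  field <- stage("detect", {
    f <- detect_anomalies(cube_filled, cfg$mode, cfg$detector,
                          cfg$include_wind)
    write_scores_csv(f, file.path(out_dir, "scores.csv"))
    f
  })

  wind <- wind_daily_from_cube(cube_filled)
  evaluation <- stage("evaluate", {
    ev <- evaluate_anomalies(field, scenario$grid, wind$direction,
                             wind$speed, cfg$selection,
                             cfg$angle_threshold)
    write_clusters_json(ev, file.path(out_dir, "clusters.json"))
    ev
  })

  stats <- stage("explain", {
    st <- explain_corpus(cube_filled, q = cfg$explain_q)
    jsonlite::write_json(
      list(feature_counts = as.list(st$feature_counts),
           combination_counts = as.list(st$combination_counts)),
      file.path(out_dir, "explanations.json"),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(st$per_point,
                     file.path(out_dir, "explanations_per_point.csv"),
                     row.names = FALSE)
    st
  })

  if (render)
    render_maps(evaluation, scenario$grid, scenario$farm,
                file.path(out_dir, "maps"))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$|\\.png$", files)]
  manifest <- list(
    config_hash = unname(tools::md5sum(write_config_tmp(cfg))),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        sub(paste0("^", out_dir, "/?"), "",
                                            files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(scenario = scenario, cube = cube,
                 cube_filled = cube_filled, field = field,
                 evaluation = evaluation, stats = stats,
                 manifest = manifest))
}

# Serialize the config deterministically for hashing.
write_config_tmp <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  writeLines(deparse(cfg), tmp)
  tmp
}

# Daily wind direction/speed from the broadcast wind features of a cube
# (any grid point carries the areal value).
wind_daily_from_cube <- function(cube) {
  need <- c("wind_direction", "wind_speed")
  if (!all(need %in% cube$features))
    stop("cube carries no wind features")
  data.frame(day = seq_len(cube$n_days),
             direction = cube$values[, 1, "wind_direction"],
             speed = cube$values[, 1, "wind_speed"])
}

#' Render per-window anomaly maps
#'
#' One PNG per time window: the averaged anomaly map coloured over the
#' grid, the farm footprint dashed, and persistent points circled.
#' Cosmetic output only.
#'
#' @param evaluation An `anomaly_evaluation`.
#' @param grid The matching `grid_definition`.
#' @param farm Farm polygon data frame (`lat`, `lon`), or `NULL`.
#' @param dir Output directory.
#' @return File names, invisibly.
#' @export
render_maps <- function(evaluation, grid, farm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- evaluation$windows
  files <- character(nrow(w))
  for (i in seq_len(nrow(w))) {
    files[i] <- file.path(dir, sprintf("window_%02d-%02d.png",
                                       w$start_day[i], w$end_day[i]))
    grDevices::png(files[i], width = 800, height = 640)
    v <- evaluation$maps[[i]]
    pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
    col <- ifelse(v > 0, pal[pmax(1, ceiling(v * 64))], "grey90")
    graphics::plot(grid$lon, grid$lat, col = col, pch = 15,
                   cex = 0.6, xlab = "lon", ylab = "lat",
                   main = sprintf("days %d-%d, mean wind %.0f deg",
                                  w$start_day[i], w$end_day[i],
                                  w$mean_direction[i]))
    pers <- evaluation$persistent[[i]]
    if (length(pers))
      graphics::points(grid$lon[pers], grid$lat[pers], pch = 1,
                       cex = 1.4, col = "grey40")
    if (!is.null(farm))
      graphics::lines(farm$lon, farm$lat, lty = 2, lwd = 2)
    graphics::points(w$centroid_lon[i], w$centroid_lat[i], pch = 3,
                     cex = 2, lwd = 2, col = "blue")
    grDevices::dev.off()
  }
  invisible(files)
}
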