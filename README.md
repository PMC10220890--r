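# windwake

Anomaly-based monitoring of offshore wind farm effects on the sea
surface, from routinely available data.

Offshore wind farms alter their marine surroundings: foundations force
tidal currents into turbulent wakes, and the reduced-wind wake behind the
rotors can drive upwelling/downwelling cells, changing mixing,
stratification and ultimately surface temperature, salinity, suspended
matter and chlorophyll around the farm. Ship-based campaigns that could
measure this are rare and expensive. `windwake` implements a monitoring
pipeline for scientists and monitoring agencies that needs nothing but
public data streams: satellite ocean-colour/temperature scenes, surface
fields of an operational hydrodynamic model, and wind measurements from
an in-situ platform.

The pipeline:

1. **Fusion** — all sources are placed on a regular lat/lon grid
   (Haversine nearest-neighbour adoption, k = 1, 1 km cutoff; reference
   configuration: 54.97–55.32 °N, 6.92–7.47 °E at 0.004°, an
   88 × 138 = 12,144-point grid) and on the daily satellite-overpass time
   base (window means; circular means for directions; point sources
   broadcast).
2. **Imputation** — cloud gaps in each grid point's multivariate series
   are filled by a DTW-kNN ensemble: the observed context around a gap is
   matched elastically (dynamic time warping, Sakoe–Chiba band) against
   all equally sized windows of the same series, and the k nearest
   windows' gap-aligned values are averaged; three members with context
   radii w ∈ {3, 4, 5} days are ensembled.
3. **Detection** — per-day, per-point anomaly scores from COPOD, an
   empirical-copula detector: per feature *d*, left/right tail ECDFs
   F̂ᵈ, Ĝᵈ and skewness bᵈ give
   p_L = Σᵈ −log F̂ᵈ, p_R = Σᵈ −log Ĝᵈ, p_S (skewness-picked tails), and
   score = max(p_L, p_R, p_S). Deterministic, parameter-free, and
   decomposable per feature. Temporal mode (each point's history) and
   spatial mode (each day's grid) are provided; other detectors plug in
   via `register_detector()`.
4. **Evaluation** — per day the top 3% of scores (the wind-farm-size
   equivalent; 364 ≈ 369 points on the reference grid), scaled by the
   day's score dispersion, min–max normalised, averaged over
   wind-direction windows (greedy segmentation at 45° from the running
   circular mean); per window the cluster centroid C = (Σφᵢ/n, Σλᵢ/n),
   positional standard deviation s (divisor n) and radius
   r = d_haversine(C, C + s), plus persistence flags for points selected
   on ≥ 2 days.
5. **Explanation** — for each point's highest-scoring day, per-feature
   contributions (the winning branch's −log tail probabilities, summing
   exactly to the score) against a per-feature 0.99-quantile cutoff band,
   aggregated over the grid.

A seed-controlled scenario generator (`generate_scenario()`) emulates all
sources — smooth Gaussian random fields with AR(1) day-to-day
persistence, regime-structured 10-min wind, shared cloud gaps, and an
injectable wind-gated wake plume downwind of the farm — so the entire
chain runs and is tested without any download.

## Worked example

A scaled DanTysk-like scenario (294 grid points, 31 days) with a wake
plume that perturbs the mixing signature (SST, T0, S0, TSM at 4 sd,
4 km radius, 5 km downwind of the farm) on strong-wind days:

```r
library(windwake)

cfg <- scenario_config(
  lat_min = 55.0, lat_max = 55.2, lon_min = 6.9, lon_max = 7.2,
  spacing = 0.015, n_days = 31,
  plume = list(enabled = TRUE,
               magnitudes = c(SST = 4, T0 = 4, S0 = 4, TSM = 4),
               radius_km = 4, offset_km = 5, wind_gate = 9.5),
  seed = 42)

scn    <- generate_scenario(cfg)
cube   <- fuse_scenario(scn)          # 31 x 294 x 9, 5.3% missing (clouds)
filled <- impute_cube(cube)           # complete cube, observations untouched
field  <- detect_temporal(filled)     # COPOD, 7 features, wind excluded
wind   <- scenario_daily_wind(scn)
ev     <- evaluate_anomalies(field, scn$grid, wind$direction, wind$speed)
ev$windows
#>   start_day end_day mean_direction centroid_lat centroid_lon radius_km n_points n_persistent
#> 1         1       5      314.57233     55.10897     7.041176  9.580402       34            7
#> 2         6       9      180.02240     55.14250     7.061667  2.176785       18           15
#> 3        10      12       44.69979     55.07700     7.060000  8.299313       15            1
#> 4        13      16      300.11919     55.07500     7.104474  2.548252       19           12
#> 5        17      21      135.29628     55.11000     6.990909  9.254772       33            2
#> 6        22      31      270.54030     55.09921     7.056053  8.011162       57           18
```

The plume is active on days 6–9 (wind from 180°, so the plume sits 5 km
north of the farm centroid at (55.145, 7.05)) and days 13–16 (wind from
300°, plume to the southeast). Exactly those two windows stand out: small
radius (dense cluster), many persistent points, and centroids at
(55.1425, 7.0617) and (55.0750, 7.1045) — 0.79 km and 0.91 km from the
true plume centres, on the correct downwind sides. The other windows show
diffuse selections (radius 8–10 km) scattered over the domain.

Explaining a grid point inside the plume core:

```r
p  <- 201                              # a point under the day-6..9 plume
ex <- explain_point(filled$values[, p, c("SST","CHL","TSM","u","v","T0","S0")])
ex
#> <explanation> day 8, score 19.319
#>   responsible: CHL, TSM, S0
```

The point's strongest anomaly falls on an active plume day (day 8) and
is attributed to suspended matter and salinity among others — TSM and S0
are two of the four perturbed features (CHL rides along because the
plume days are jointly unusual at this point).

`run_pipeline(run_config(scenario = cfg), "out/")` executes the same
chain end to end, writing every stage's output (`cube.csv`,
`cube_filled.csv`, `scores.csv`, `clusters.json`, `explanations.json`)
plus a checksum manifest; re-running with the same config reproduces the
checksums exactly. A thin CLI (`inst/exec/windwake`) exposes the stages
as subcommands (`simulate`, `fuse`, `impute`, `detect`, `evaluate`,
`explain`, `run-all`).

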