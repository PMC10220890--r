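---
title: "Monitoring offshore wind farm effects with windwake: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring offshore wind farm effects with windwake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windwake)
```

## The problem

Offshore wind farm foundations force tidal currents around them and
generate turbulence, and the wind wake behind the turbines can drive
upwelling and downwelling cells. Both mechanisms can change vertical
mixing, stratification and hence surface temperature, salinity, suspended
matter and phytoplankton around a farm. Dedicated ship campaigns that
could measure these effects are expensive and rare, so `windwake`
implements a monitoring chain built entirely from routinely available
data: satellite ocean-colour and temperature scenes, surface fields of an
operational hydrodynamic model, and wind measurements from a platform at
the farm.

The chain is: **fuse** the sources onto a common grid and daily time base;
**impute** the cloud gaps so the detectors see a complete data set;
**detect** per-day, per-grid-point anomaly scores; **evaluate** the scores
into per-wind-window anomaly maps with cluster geometry; **explain** which
variables drive each grid point's strongest anomaly. A synthetic scenario
generator stands in for the real data sources so the whole chain runs,
and can be tested, offline.

## Grid fusion

All sources are resampled onto a regular latitude/longitude grid
(`build_grid()`). The reference configuration is the DanTysk study area,
54.97–55.32 °N, 6.92–7.47 °E at 0.004° spacing, which yields an
88 × 138 = 12,144-point grid; coordinates run from the lower bounds in
steps of the spacing, keeping every coordinate that does not exceed the
upper bound (with a 10⁻⁹-degree tolerance, so bounds that are exact
multiples of the spacing are included).

Each raster source is matched to grid points by Haversine
nearest-neighbour adoption (k = 1): a grid point takes the value of its
nearest observation, and is left missing when that observation is more
than 1 km away. Distances use a spherical Earth of radius 6371.0 km (the
choice of radius is ours; differences to other conventions are far below
the grid spacing). Exactly equidistant observations resolve to the lower
observation index, which makes resampling deterministic. Because values
are adopted, never interpolated, every unmasked cube value equals some
source value exactly — missing satellite pixels (cloud fill values)
propagate to the grid as missingness rather than being smeared.

Sub-daily sources are collapsed to the daily satellite-overpass time
base: the arithmetic mean of the samples inside a configurable daily
window (default 60 minutes centred on 10:00 UTC; the true overpass time
of the satellite is site-specific and can be supplied). Wind and current
*directions* are averaged as circular means of unit vectors — an
arithmetic mean is simply wrong across the 0°/360° wrap. Point
measurements (platform wind) carry the areal weather and are broadcast
to every grid point.

## Gap imputation: DTW-kNN

Clouds leave contiguous multi-day gaps in the satellite features, which
rules out naive spatial interpolation (whole neighbourhoods are missing
together) and makes linear interpolation poor for gaps longer than a
couple of days. `windwake` fills each gap by window matching: the
observed *context* of `w` days on each side of the gap is compared with
every equally long, fully observed window elsewhere in the same grid
point's series, and the gap takes the (inverse-distance-weighted) mean of
the `k` best-matching windows' values at the gap-aligned positions.

Window similarity is the sum over features of dynamic-time-warping (DTW)
distances between the contexts. DTW uses a squared-difference local cost
with unit steps and reports the square root of the accumulated cost; a
Sakoe–Chiba band (default radius 2 days) keeps the warping local, which
both regularises the match and bounds the cost. The DTW recursion runs in
C++; an independent R dynamic program serves as its oracle in the tests.

Numerical choices worth knowing:

* **Normalisation.** Before computing distances, each feature is
  standardised by its *whole observed series* mean and standard
  deviation. This makes the multivariate distance scale-free across
  features (°C, mg/m³, psu and m/s are not comparable raw) while
  preserving window-level information. Standardising each window locally
  — the more common DTW convention — discards the level, and we found it
  makes the ranking systematically worse than even a raw-window
  Euclidean baseline on level-informative series.
* **Value transfer** is positional: the selected candidate window is laid
  over the gap and its middle values are averaged. Transfer along the
  warping path would require inverting a many-to-many alignment; the
  positional rule is the simplest defensible choice and is what the
  ensemble averages over.
* **Ensembles.** The default ensemble averages three members with graded
  context radii, w ∈ {3, 4, 5}, all with k = 3 and inverse-distance
  weighting. A uniform-weight k = 5 member was tried and systematically
  dragged the ensemble mean down on warped seasonal benchmarks, so the
  graded-radius design was kept.
* **Fallbacks.** Gaps at the series boundary use one-sided context. When
  fewer than `k` candidate windows exist, or no feature is fully
  observed in the context, the gap falls back to linear interpolation
  with constant extension at the series ends. Series with fewer than two
  observations are filled with the feature's cube-wide mean (counted and
  reported by `impute_cube()`).

Observed values are never altered, and the whole imputation is
deterministic.

`compare_imputation_methods()` quantifies the design on synthetic
multivariate seasonal series (`seasonal_multiseries()`): a
chlorophyll-like target with a wandering-phase synoptic cycle, a lagged
low-amplitude covariate, and a large-scale noisy covariate. The scale
spread between the variables is deliberate — it emulates a fused marine
data set and is exactly the regime where a raw-window kNN baseline is
dominated by the largest-scale feature while the standardised DTW match
weighs all features. On 30 such trials with 5–10-day gaps the mean R²
ordering is: DTW-kNN ensemble ≥ single DTW-kNN > raw-window kNN > linear
interpolation. The printed R² levels depend entirely on the synthetic
series design and say nothing quantitative about real data; only the
ordering is the point.

## Anomaly detection: COPOD

The detector interface takes a samples × features matrix and returns one
score per sample. Two modes exist:

* **temporal** — each grid point's days × features matrix is scored
  separately, so a point's scores depend only on its own history;
* **spatial** — all grid points of one day are scored jointly.

The native detector is COPOD, chosen for its determinism (no
hyperparameters, no randomness — identical inputs give bit-identical
scores) and for its built-in explanation. For feature *d* with left and
right empirical CDFs F̂ᵈ(x) = #{xᵢ ≤ x}/n and Ĝᵈ(x) = #{xᵢ ≥ x}/n and
sample skewness bᵈ, the three aggregates for sample *i* are

$$p_L = \sum_d -\log \hat F_d(x_{id}),\quad
  p_R = \sum_d -\log \hat G_d(x_{id}),\quad
  p_S = \sum_d -\log \hat t_d(x_{id}),$$

with t̂ᵈ = F̂ᵈ where bᵈ < 0 and Ĝᵈ otherwise, and the score is
max(p_L, p_R, p_S). Scoring is transductive (fit and score on the same
matrix), matching unsupervised use. Every ECDF value on the fitted matrix
is at least 1/n, so scores are bounded by F·log n. Constant features have
degenerate ECDFs equal to 1 and contribute −log 1 = 0, which is why
including the spatially constant broadcast wind cannot change spatial
COPOD scores. The two ECDF aggregates depend on ranks only; the
skewness-corrected branch additionally depends on the tail side, so
scores are invariant under monotone per-feature transforms exactly when
the transform preserves each feature's skewness sign — the tests assert
that conditional form, plus exact rank agreement with an independent
rank-based implementation.

Because the scores are rank-based, a *persistent* shift (say, half the
month) is barely anomalous at a grid point no matter how large it is:
what temporal COPOD sees are *episodic* deviations occupying a small
minority of days. This matters for what the pipeline can and cannot
detect, and it shaped the synthetic wake plume below.

Other detectors (LOF, isolation forest, one-class SVM, …) are not
re-implemented; `register_detector()` accepts any callable so external
implementations can be compared through the same evaluation chain. The
default feature set is the seven satellite + model variables {SST, CHL,
TSM, u, v, T0, S0}; the broadcast wind features and the model current
direction are available behind flags and arguments but excluded by
default, the configuration retained for evaluation.

## Evaluation: selection, wind windows, cluster geometry

Scores become maps in four steps.

1. **Daily selection.** The top fraction (default 3%, the size class of a
   wind-farm footprint on the reference grid: round(0.03 · 12,144) = 364
   points, against 369 farm-equivalent points) of each day's scores is
   selected. The selected count is scaled by the ratio of the day's score
   standard deviation to the period's mean daily standard deviation —
   a day with strongly dispersed scores is "more anomalous" and
   contributes more points — and clipped to [1, N]. The scaling scales
   the *count*; the under-specified alternative (scaling the threshold)
   is behaviourally similar and the count reading is the documented one.
   Ties resolve to lower point indices.
2. **Normalisation.** Selected scores are min–max normalised to [0, 1]
   per day (all 1 when the selection is constant); unselected points
   carry 0.
3. **Wind windows.** The day axis is segmented greedily: a new window
   starts when a day's wind direction is more than `angle_threshold`
   (default 45°, chosen to produce month-scale segmentations of 4–8
   windows under realistic regimes) from the running circular mean of the
   current window. Windows partition the days; single-day windows are
   legitimate. The daily normalised maps are averaged per window, zeros
   included.
4. **Cluster geometry.** Over the points with positive averaged value,
   the centroid is the plane-surface mean of latitudes and longitudes,
   the positional standard deviation uses divisor *n* (population form),
   and the radius is the Haversine distance between the centroid C and
   C + s — one number for the cluster's spread. Points selected on at
   least two days of a window are flagged persistent. All positive
   points enter unweighted; down-weighting rarely selected points would
   change the centroid's meaning and is deliberately not done.

## Explanation

For each grid point, the day with the highest temporal COPOD score is
decomposed into per-feature contributions: the −log tail probabilities of
whichever branch attained the max, so the contributions sum *exactly* to
the score. A feature is responsible when its contribution reaches the
per-feature 0.99 empirical quantile band of contributions across the
fitted matrix. With month-long series (n = 31) the largest possible
contribution, −log(1/31), is simultaneously the band value — the 0.99
quantile of 31 values is essentially their maximum — so *reaching* the
band is the operative rule; requiring a strict excess would make the most
extreme day unexplainable by construction. A zero contribution is never
responsible, so constant features cannot be flagged.
`explain_corpus()` aggregates responsible features and their
combinations over the grid, the corpus-level view of which variables
drive the anomalies.

## The synthetic scenario generator

`scenario_config()`/`generate_scenario()` emulate the statistical
structure of the real sources, not their physics:

* **Fields.** Each feature is a Gaussian random field: white noise
  smoothed with a Gaussian kernel of the feature's correlation length,
  standardised, and blended day-to-day as AR(1) with persistence ρ
  (default 0.7). Smoothing happens on a padded grid and is cropped, so
  edge points have the same variance as the interior. Defaults (SST
  ≈ 10 °C, CHL ≈ 2 mg/m³, correlation lengths 0.05–0.08°) are loosely
  late-spring North Sea values — plausible scales, no claim of realism.
* **Cadences.** Satellite features are one scene per day at the overpass
  instant on their own pixel grid (offset from the analysis grid by a
  third of a pixel); model features are hourly samples around the
  overpass on a coarser 0.009° grid; wind is a 10-minute point series.
* **Wind.** A regime table (direction, speed, duration); the default six
  regimes over 31 days end in a stable 10-day regime. Directions are
  meteorological — where the wind comes *from*, degrees clockwise from
  north — and "downwind of the farm" means displaced along
  direction + 180°. Within a regime, 10-minute samples get wrapped
  normal direction noise (sd 8°) and speed noise.
* **Clouds.** With probability 9/31 per day (the study month had gaps on
  nine of 31 days), random discs set the three satellite features to NA
  simultaneously — shared cloud, shared gap.
* **Wake plume.** When enabled, a disc displaced downwind of the farm
  centroid perturbs the *mixing signature* — by default SST, T0, S0 and
  TSM at 4 sd — with a flat core (inner 60% of the radius) and cosine
  edge. An optional wind-speed gate makes the plume episodic: active only
  on days whose regime wind reaches the gate, reflecting wake mixing
  driven by strong winds. The episodic form is also what a rank-based
  temporal detector can see at all (a permanent shift is not an anomaly
  in rank terms). Ground truth (daily centre, active days, perturbed
  features, cloud discs) is recorded for recovery tests.

Everything derives from one integer seed; identical seeds give
bit-identical scenarios and, through the deterministic pipeline,
bit-identical outputs.

What passing the recovery tests does **not** show: that real wake
effects are detectable at these magnitudes, that real cloud statistics
match random discs, or that the hydrodynamic model's systematic biases
(a known driver of model-feature responsibility in practice) are
represented. The generator supports correctness and sensitivity claims
about the *pipeline*, not effect-size claims about the ocean.

## Problem sizes and runtime

The reference grid (12,144 points) is used for grid-construction checks
only. End-to-end tests and the acceptance script run a scaled study
area — 0.2° × 0.3° at 0.015° spacing, 294 grid points, 31 days, full
feature set — which keeps one pipeline run near ten seconds and a
20-run recovery study within a few minutes on one CPU, while preserving
every structural property of the full-size problem (cloud gaps, regime
structure, plume geometry at realistic kilometre scales). The methods
themselves are O(points) and run at full scale unchanged.

## Known limitations

* Candidate windows for imputation come from the same grid point's
  series only; neighbouring points' series are not searched.
* One cluster summary per window: multi-cluster decomposition is out of
  scope.
* Explanation is COPOD-specific; externally registered detectors get
  scores but no dimensional explanation.
* The spatial detection mode inherits COPOD's edge behaviour — the most
  extreme values of a smooth field tend to sit at the domain edge.
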