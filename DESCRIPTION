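Package: windwake
Title: Anomaly-Based Monitoring of Offshore Wind Farm Effects on the Sea Surface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses multi-source gridded marine observations (satellite ocean
    colour and temperature, hydrodynamic model surface fields, in-situ wind)
    onto a common geographic grid, fills cloud-induced gaps in per-grid-point
    multivariate time series with a dynamic-time-warping k-nearest-neighbour
    ensemble, scores spatiotemporal anomalies with an empirical-copula
    detector (COPOD), and summarises anomaly clusters (centroid, dispersion,
    radius, persistence, responsible features) relative to a wind farm
    footprint and the prevailing wind direction. Includes a seed-controlled
    synthetic scenario generator so the full pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
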