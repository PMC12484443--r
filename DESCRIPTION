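Package: accessim
Title: Least-Cost Travel Time and Equity Analysis for Health Facility Access
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models geographic accessibility to health services on raster
    grids. Estimates road-class travel speeds from GPS trajectories by
    nearest-segment map matching, merges roads, land cover and
    slope-adjusted walking speeds into per-scenario friction surfaces,
    accumulates least-cost travel time from facility sets with a
    multi-source Dijkstra over 8- or 16-connected grids, and summarizes
    population-weighted coverage within travel-time thresholds together
    with wealth-quintile (equiplot) and urbanicity-gradient inequality
    tables. Ships a synthetic landscape generator with known ground truth
    so every stage is testable without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
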