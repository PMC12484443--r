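# accessim

Least-cost travel time and equity analysis for geographic access to
health facilities.

`accessim` answers a planning question that recurs across maternal-health
research in rapidly urbanizing regions: *how long does it take women to
reach the nearest facility offering childbirth care, and how unequally is
that time distributed across wealth and settlement gradients?* It
implements the full analysis chain on 30 m raster grids:

1. **Speed survey** — per-road-class speed distributions (mean / min /
   max / sd, km/h) estimated from timestamped GPS trajectories by
   nearest-segment map matching.
2. **Friction surface** — roads rasterized over land cover into a
   per-cell speed raster; water is an absolute barrier; walking speeds
   are slope-adjusted with the normalized Tobler hiking function
   `f(s) = exp(-3.5·|s + 0.05|) / exp(-3.5·0.05)`.
3. **Cost accumulation** — multi-source Dijkstra over the 8- (or
   16-)connected grid. A move from cell *a* to neighbour *b* at distance
   *d* costs `d·(½/v_a + ½/v_b)`, each half travelled under that cell's
   regime, giving the travel-time surface `T(c) = min over facilities of
   the least-cost path time`, in minutes. Three speed scenarios
   (minimum / average / maximum observed speed) bracket worst-case to
   best-case conditions, for four facility strata (all, public,
   hospitals, public hospitals).
4. **Coverage and equity** — population-weighted percentage of women of
   childbearing age (WoCBA) within 30/60/120 minutes, zonal summaries,
   wealth-quintile equiplot tables from nearest-point relative-wealth
   matching, and urbanicity-band travel-time gradients.

A seeded synthetic-landscape generator (DEM, land cover, classed road
network, facilities, population, wealth points, urbanicity, GPS traces —
all with retained ground truth) makes every stage testable without any
external geodata.

## Worked example

```r
library(accessim)
res <- run_pipeline(pipeline_config(seed = 42))

subset(as.data.frame(res$speeds), class_kind == "road")
#  class_kind        class mean   min  max       sd    n
#        road      primary 18.0 17.75 18.0 0.024259  477
#        road  residential 12.6 10.84 12.6 0.068854 2663
#        road    secondary 15.1 15.00 15.1 0.004341 1028
#        road      service  9.6  9.59  9.6 0.000295 1510
#        road     tertiary 15.3 14.99 15.3 0.009339 1196
#        road        trunk 20.3 12.91 20.4 0.613061  322
#        road unclassified 17.1 16.24 17.1 0.063963  185
#        road       others  5.0  4.00  6.0       NA    0
```

The estimated class means sit on the generator's ground truth (18.0,
12.6, ... km/h); the small downward spread below each mean comes from
trajectory points that straddle polyline corners, exactly as real GPS
pairs do. The `others` row is fixed at walking pace, not estimated.

```r
subset(res$coverage, zone_level == "study_area" & threshold == 30 &
         stratum %in% c("all", "hospitals"))[,
  c("stratum", "scenario", "threshold", "pct_wocba")]
#    stratum scenario threshold pct_wocba
#        all  minimum        30      85.8
#  hospitals  minimum        30      85.8
#        all  average        30      86.3
#  hospitals  average        30      86.1
#        all  maximum        30      86.9
#  hospitals  maximum        30      86.4
```

`pct_wocba` is the share of women within 30 minutes of the nearest
facility of that stratum under each speed scenario; unreachable women
(e.g. enclosed by water) stay in the denominator. Coverage is
guaranteed non-decreasing in the threshold, non-increasing as the
facility stratum shrinks, and ordered across scenarios
(maximum ≥ average ≥ minimum) — these invariants are tested on random
landscapes.

`res$tt` holds the twelve travel-time surfaces, `res$equiplot` the
per-quintile means behind an equiplot (`plot_equiplot()` draws it), and
`res$urbanicity_table` the settlement-gradient summary. With `out_dir`
set, all surfaces are written as ASCII grids and all tables as CSV,
plus a JSON QC report.

A thin command-line front end with verbs `synth`, `speeds`,
`traveltime`, `coverage`, `equity` and `run` is installed at
`system.file("cli/accessim.R", package = "accessim")`.

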