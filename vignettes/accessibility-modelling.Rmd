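---
title: "Modelling geographic accessibility to health facilities with accessim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling geographic accessibility to health facilities with accessim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accessim)
```

## The model

`accessim` estimates, for every 30 m grid cell, the minimum time needed
to reach the nearest health facility of a given stratum, and summarizes
how that time is distributed over population, wealth and settlement
gradients.

The travel model is a least-cost path on the raster grid. Each cell
carries a traversal speed in m/s, merged from two sources: cells crossed
by a road take the road class's speed and are traversed motorized
(except the `others` class — footways and similar — which is walked);
all remaining cells take their land-cover class's walking speed. Water
is an absolute barrier (speed 0) in every scenario. A move between
adjacent cells $a \to b$ over distance $d$ (cell size, $\sqrt2$ times
that on diagonals, $\sqrt5$ for knight moves at connectivity 16) costs

$$ t_{a\to b} = d\left(\frac{1}{2\,v_a} + \frac{1}{2\,v_b}\right), $$

i.e. each half of the move is travelled under that cell's regime, so a
boundary move between a road and a swamp costs the mean of the two
regimes. Travel time is the minimum cumulative cost from any facility
cell, computed by a compiled multi-source Dijkstra. Because the
per-move cost is symmetric, the surface is identical whether one thinks
of women travelling to facilities or vice versa.

### Slope-adjusted walking

Walking speeds are adjusted anisotropically by the slope of each move,
$s = (z_b - z_a)/d$ (signed, in the direction of travel), using the
normalized Tobler hiking function

$$ f(s) = \frac{e^{-3.5\,|s + 0.05|}}{e^{-3.5 \times 0.05}}, $$

so $f(0) = 1$ exactly — tabulated walking speeds are flat-ground
speeds — with a maximum of $e^{0.175} \approx 1.19$ on a gentle 5%
descent. The adjustment applies at move time (uphill and downhill moves
between the same two cells cost differently), only to pedestrian cells:
motorized speeds come from GPS observation on real terrain and already
embody it. Tobler's function is the de-facto standard in this family of
accessibility analyses; the normalization is our choice, made so the
speed table keeps a single, interpretable meaning.

### Speed scenarios

The per-class speed table carries three columns — minimum, mean,
maximum — estimated from GPS traces. Each defines a scenario
(`minimum`, `average`, `maximum`) used for a full accumulation run, so
results come as a worst-case/typical/best-case continuum rather than a
point estimate. Minimum and maximum are the untrimmed extremes of
observed speeds: urban congestion makes genuinely slow observations
informative, so we do not trim to percentiles. Combined with the four
facility strata (all facilities, public-sector only, hospitals, public
hospitals) the full design yields twelve travel-time surfaces.

## Speed estimation from trajectories

GPS points are matched to the nearest road segment within a buffer
(default 20 m, a typical urban GPS error envelope); distance ties break
to the smallest segment id so matching is deterministic. Consecutive
points matched to one segment (or one class) yield speed observations
as straight-line distance over elapsed time. Pairs with a time gap
above 30 s break the chain (the receiver lost fix or the trip paused),
zero elapsed time is skipped with a warning, and observations above an
outlier cap of 120 km/h are dropped and counted in the QC report —
faster-than-physically-plausible jumps are GPS glitches, not traffic.
The sd column uses the sample (n−1) denominator, the convention for
survey estimates. Land-cover walking speeds are not estimated from
vehicle traces; they come from a fixed bundled table
(`default_landcover_speeds()`).

Straight-line pair distances slightly undershoot path distance when a
pair straddles a polyline corner, biasing speeds marginally downward —
visible in the example below as class minima a little under the
generator truth. On straight segments recovery is exact, which is how
the estimator is validated.

## The synthetic landscape

Every downstream stage is tested against generated study areas with
known ground truth, emulating a coastal West African metropolitan
area:

* **DEM** — a sum of Gaussian bumps (default 4 bumps, 5–40 m amplitude
  over a 10 m base). Bump parameters are retained, so slopes have a
  closed form for tests.
* **Land cover** — seven classes (water, trees, flooded vegetation,
  crops, built area, rangeland, bare ground). A smooth random field is
  ranked and sliced so configured class fractions are honoured to one
  cell, with the wettest classes at the field minima — giving
  contiguous water bodies rather than salt-and-pepper noise. Defaults:
  45% built area, 8% water.
* **Roads** — sequentially grown classed polylines; the first spans the
  extent and every later segment starts on an existing one, so the
  network is connected. Default counts follow a residential-dominated
  urban hierarchy.
* **Facilities** — exact requested counts per level and sector group;
  the default registry has 292 facilities (13 hospitals of which 10
  public; 75 health centers, 69 public; 48 medical centers, 3 public;
  156 clinics, 2 public), matching the scale of a real metropolitan
  childbirth-care registry. The public group is split
  government:faith-based at 5:1 by largest remainder. Placement weights
  are proportional to population density to the power of a clustering
  factor, restricted to road-adjacent cells when a network is supplied
  (so no facility is stranded in a swamp).
* **Population** — Gaussian settlement kernels over a uniform
  background, rescaled to sum exactly to the configured WoCBA total
  (default 50,000 at the default 60×60 grid).
* **RWI points** — a regular lattice (default spacing 240 m; the
  generator refuses spacings that fit fewer than 5 points, since
  quintiles would be undefined) carrying a west–east wealth gradient
  plus Gaussian noise; the gradient is retained as ground truth.
* **Urbanicity** — population density box-smoothed (radius 3 cells) and
  thresholded at configured quantiles into ordered bands
  (`very_low_density` … `city`). The band taxonomy is configurable
  because no standard fixes it; the default seven-band continuum spans
  hamlet to city core.
* **Trajectories** — trips follow one road segment end-to-end at the
  class's ground-truth mean speed, sampled at a fixed interval, with
  optional i.i.d. Gaussian positional noise per coordinate.

All generators are pure functions of `(inputs, seed)`; a missing seed
is an error, not a silent `Sys.time()` default.

What the generator does *not* emulate: time-of-day congestion cycles,
one-way streets and turn restrictions, facility bypassing behaviour,
seasonal flooding, and OSM-style incompleteness. Passing tests
therefore validate the computational chain — not the fidelity of any
particular real-world dataset fed into it.

## Aggregation choices

* **Zone membership** is by cell centre, with boundary ties to the
  lexicographically smallest zone id. Every cell belongs to exactly one
  zone per level, which makes aggregation exact: commune-level covered
  population sums to the study-area figure, and the test suite asserts
  it.
* **Zonal means** are unweighted over populated, reachable cells; a
  population-weighted mean is emitted alongside (`wmean_tt`) since
  which statistic a GIS "zonal mean" denotes varies by tool.
* **Coverage denominators** include unreachable populated cells:
  coverage is a claim about all women in a zone, not about those who
  happen to have a route.
* **Wealth quintiles** are population-weighted — each quintile holds
  one fifth of women, not one fifth of cells, the epidemiological
  convention for equiplots. A cell straddling a boundary goes to the
  quintile containing its cumulative-weight midpoint,
  $q = \lceil (W_{<} + w/2) / (W/5) \rceil$; equal wealth values stay
  contiguous and the assignment is invariant to cell order. Equiplot
  rows report the weighted mean and, because the mean/median choice is
  genuinely open in this literature, a weighted median column too.

## Numerical choices and degenerate inputs

* Travel time is accumulated in seconds as doubles and only converted
  to minutes at the end; rounding to one decimal happens at reporting
  time, never internally.
* Unreachable cells are `NA` in surfaces (and compare as $+\infty$ in
  monotonicity checks).
* A facility whose cell is a barrier snaps to the nearest passable cell
  within 3 cells (90 m — geocoding error scale), else is dropped with a
  warning that the QC report captures. A stratum selecting zero
  facilities is an error, as is an entirely unreachable source set.
* Road rasterization is supercover — every cell whose boundary the
  segment touches is marked, both sides when a segment runs exactly
  along a gridline — so one-cell-wide diagonal roads stay connected
  under 8-connectivity. Where classes overlap in a cell the fastest
  mean speed wins.
* The slope factor is computed as `exp(-3.5*(|s+0.05|-0.05))`, an
  algebraically identical grouping chosen so the flat-ground anchor is
  exactly 1 in floating point.
* Default connectivity is 8; 16 adds knight moves, reducing the octile
  anisotropy of grid paths at the cost of letting moves hop one-cell
  barriers diagonally — which is why barrier-enclosure guarantees are
  stated for connectivity 8.

## Validation strategy and problem sizes

The test suite validates the accumulation core against an independently
built shortest-path oracle: the move graph is materialized edge by edge
in R and solved with `igraph::distances`, sharing no code with the
compiled Dijkstra. Agreement is required to 1e-9 relative on 100 random
grids up to 12×12 with random barriers, walking masks and terrain, under
both connectivities. Closed forms (octile distance on uniform friction,
the 1×3 walking grid, Tobler anchors) pin absolute scales, and
parameter-recovery tests confirm the speed survey reproduces generator
truth exactly on clean straight-segment traces. Property tests assert
the scenario/stratum/threshold monotonicities on 20 random landscapes.
Default test and pipeline sizes (20–60 cells per side, tens of
facilities, ~50 trips) were chosen as the smallest landscapes that
exercise every code path with comfortably non-degenerate statistics;
the compiled core handles much larger grids — cost grows as
$O(n \log n)$ in cells.

## Known limitations

* No explicit transport-mode switching: a cell is walked or driven by
  its own regime, so walk-to-road-then-drive emerges implicitly from
  the surface, without modelling waiting or transfer time.
* Nearest-facility travel time only; bypassing and referral chains are
  out of scope.
* Straight-line pair speeds under-estimate around sharp polyline
  corners (see above); full HMM map matching is out of scope.
* The ASCII-grid raster interface is single-band text; pyramid/tiled
  formats for very large grids are not provided.
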