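supercover_cells <- function(coords, grid) {
  # all (row, col) cells touched by a polyline, supercover: cells whose
  # boundary or interior the line crosses, both sides when the line runs
  # exactly along a gridline, all four neighbours at an exact corner hit
  eps <- 1e-9
  n_rows <- grid$n_rows; n_cols <- grid$n_cols
  acc <- new.env()
  mark <- function(row, col) {
    if (row >= 1 && row <= n_rows && col >= 1 && col <= n_cols)
      assign(sprintf("%d_%d", row, col), TRUE, envir = acc)
  }
  mark_at <- function(u, v) {
    # grid units: u in [0, n_cols], v in [0, n_rows] (v from top)
    us <- if (abs(u - round(u)) < eps && round(u) >= 1 && round(u) <= n_cols - 1)
      c(round(u), round(u) + 1) else floor(u) + 1
    vs <- if (abs(v - round(v)) < eps && round(v) >= 1 && round(v) <= n_rows - 1)
      c(round(v), round(v) + 1) else floor(v) + 1
    for (col in us) for (row in vs) mark(row, col)
  }
  top <- grid$origin_y + n_rows * grid$cell_size
  for (i in seq_len(nrow(coords) - 1L)) {
    u0 <- (coords[i, 1] - grid$origin_x) / grid$cell_size
    u1 <- (coords[i + 1, 1] - grid$origin_x) / grid$cell_size
    v0 <- (top - coords[i, 2]) / grid$cell_size
    v1 <- (top - coords[i + 1, 2]) / grid$cell_size
    ts <- c(0, 1)
    if (abs(u1 - u0) > eps) {
      ks <- seq(ceiling(min(u0, u1)), floor(max(u0, u1)))
      ts <- c(ts, (ks - u0) / (u1 - u0))
    }
    if (abs(v1 - v0) > eps) {
      ks <- seq(ceiling(min(v0, v1)), floor(max(v0, v1)))
      ts <- c(ts, (ks - v0) / (v1 - v0))
    }
    ts <- sort(unique(clamp(ts, 0, 1)))
    mids <- (ts[-1] + ts[-length(ts)]) / 2
    for (t in c(ts, mids))
      mark_at(u0 + t * (u1 - u0), v0 + t * (v1 - v0))
  }
  keys <- ls(acc)
  if (!length(keys)) return(cbind(row = integer(), col = integer()))
  parts <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  cbind(row = as.integer(parts[, 1]), col = as.integer(parts[, 2]))
}

#' Rasterize a road network onto the analysis grid
#'
#' Supercover rasterization: every cell whose boundary or interior a
#' segment crosses carries that segment's road class, so thin diagonal
#' roads stay connected on the grid. Where several classes cross one cell,
#' the class with the highest mean speed in `table` wins.
#'
#' @param roads a `road_network` (possibly empty: all-nodata result).
#' @param spec the target [grid_spec()].
#' @param table a `speed_table` supplying the mean speeds used for the
#'   overlap priority rule (default [reference_road_speeds()]).
#' @return an [acc_raster()] of integer class codes (index into the
#'   `classes` attribute, the eight road classes); `NA` = no road.
#' @export
rasterize_roads <- function(roads, spec, table = reference_road_speeds()) {
  m <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
  segs <- roads$segments
  if (length(segs)) {
    means <- scenario_speed(table, "road",
                            vapply(segs, function(s) s$road_class,
                                   character(1)), "average")
    for (j in order(means)) {  # slow first, fastest class overwrites
      cells <- supercover_cells(segs[[j]]$coords, spec)
      if (nrow(cells))
        m[cells] <- match(segs[[j]]$road_class, ROAD_CLASSES)
    }
  }
  out <- acc_raster(spec, m, layer = "road_class")
  attr(out, "classes") <- ROAD_CLASSES
  out
}

#' Travel-speed scenario
#'
#' Validates one of the three scenarios that select a column of the speed
#' table: "minimum" (per-class slowest observed speed, worst case),
#' "average" (mean), "maximum" (fastest observed, best case).
#'
#' @param name scenario name.
#' @return the matched name, classed `scenario`.
#' @export
scenario <- function(name = c("minimum", "average", "maximum")) {
  structure(match.arg(name), class = "scenario")
}

#' Merge roads and land cover into a per-cell speed raster
#'
#' Road cells take the road class's scenario speed with motorized
#' movement; the "others" road class (footways etc.) moves at walking
#' pace and is treated as pedestrian. Cells without a road take the
#' land-cover scenario speed and are pedestrian. Water has speed 0 and is
#' an absolute barrier in every scenario.
#'
#' @param road_raster class-code raster from [rasterize_roads()].
#' @param landcover land-cover [acc_raster()] with codes as in
#'   [accessim_vocab()].
#' @param table a `speed_table` covering every class present.
#' @param scen a [scenario()] or scenario name.
#' @return object of class `speed_raster`: list with `grid`, `speed`
#'   (m/s matrix, 0 = barrier), `is_walking` (logical matrix), `scenario`.
#' @export
build_speed_raster <- function(road_raster, landcover, table,
                               scen = scenario("average")) {
  if (!inherits(scen, "scenario")) scen <- scenario(scen)
  grid <- check_same_grid(road_raster, landcover)
  lc_codes <- sort(unique(as.vector(landcover$values)))
  lc_codes <- lc_codes[!is.na(lc_codes)]
  known <- unname(LANDCOVER_CLASSES)
  if (length(bad <- setdiff(lc_codes, known)))
    stop("unknown land-cover class code(s): ", paste(bad, collapse = ", "))
  code_to_name <- names(LANDCOVER_CLASSES)[match(as.vector(landcover$values),
                                                 LANDCOVER_CLASSES)]
  lc_kmh <- scenario_speed(table, "landcover", code_to_name, unclass(scen))

  rd_idx <- as.vector(road_raster$values)
  rd_name <- ROAD_CLASSES[rd_idx]
  rd_kmh <- rep(NA_real_, length(rd_idx))
  has_road <- !is.na(rd_idx)
  if (any(has_road))
    rd_kmh[has_road] <- scenario_speed(table, "road", rd_name[has_road],
                                       unclass(scen))

  kmh <- ifelse(has_road, rd_kmh, lc_kmh)
  if (anyNA(kmh))
    stop("cells with neither road class nor known land cover present")
  walking <- !has_road | (has_road & rd_name == "others")
  structure(list(grid = grid,
                 speed = matrix(kmh / 3.6, grid$n_rows, grid$n_cols),
                 is_walking = matrix(walking, grid$n_rows, grid$n_cols),
                 scenario = unclass(scen)),
            class = "speed_raster")
}

#' @export
print.speed_raster <- function(x, ...) {
  cat(sprintf("<speed_raster '%s'> %d x %d; %.0f%% walking, %.0f%% barrier\n",
              x$scenario, x$grid$n_rows, x$grid$n_cols,
              100 * mean(x$is_walking), 100 * mean(x$speed == 0)))
  invisible(x)
}

#' Slope adjustment factor for walking speed
#'
#' Normalized Tobler hiking function: `exp(-3.5 * |s + 0.05|) /
#' exp(-3.5 * 0.05)` for signed slope `s` (rise/run in the direction of
#' travel). The normalization anchors flat ground at factor 1, so
#' tabulated walking speeds are flat-ground speeds; the factor peaks at
#' `exp(0.175)` on a gentle -5% descent and decays exponentially on
#' steeper grades either way. Applied to pedestrian cells only —
#' motorized speeds are observed on real terrain and take factor 1.
#'
#' @param slope signed rise/run, finite, |slope| < 10.
#' @return multiplicative factor on walking speed, same length as `slope`.
#' @export
slope_factor <- function(slope) {
  if (any(!is.finite(slope))) stop("slope must be finite")
  if (any(abs(slope) >= 10)) stop("|slope| must be < 10 (rise/run)")
  # algebraically exp(-3.5*|s+0.05|)/exp(-3.5*0.05); this grouping makes
  # the flat-ground anchor exp(0) = 1 exact in floating point
  exp(-3.5 * (abs(slope + 0.05) - 0.05))
}
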