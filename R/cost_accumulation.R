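#' Filter a facility registry to an analysis stratum
#'
#' The four strata of the study design: `all` facilities; `public`
#' (government plus faith-based sectors); `hospitals` (hospital level,
#' any sector); `public_hospitals` (both filters).
#'
#' @param registry a `facility_registry`.
#' @param stratum one of `"all"`, `"public"`, `"hospitals"`,
#'   `"public_hospitals"`.
#' @return the filtered `facility_registry`; errors if no facility is
#'   left (downstream accumulation needs at least one source).
#' @export
select_stratum <- function(registry, stratum = FACILITY_STRATA) {
  stratum <- match.arg(stratum, FACILITY_STRATA)
  keep <- switch(stratum,
                 all = rep(TRUE, nrow(registry)),
                 public = registry$sector %in% c("public_government",
                                                "public_fbo"),
                 hospitals = registry$level == "hospital",
                 public_hospitals = registry$level == "hospital" &
                   registry$sector %in% c("public_government", "public_fbo"))
  out <- registry[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("stratum '", stratum, "' selects no facilities")
  facility_registry(out)
}

snap_sources <- function(speed, registry, max_snap = 3) {
  # facility -> containing cell; barrier cells snap to the nearest
  # passable cell within max_snap cells (Euclidean, ties row-major),
  # else the facility is dropped with a warning
  g <- speed$grid
  rc <- xy_to_cell(g, registry$x, registry$y)
  outside <- is.na(rc$row)
  if (any(outside))
    warning(sum(outside), " facility(ies) outside the grid extent dropped")
  cells <- matrix(NA_integer_, nrow(registry), 2)
  dropped <- 0L
  for (i in which(!outside)) {
    r <- rc$row[i]; c <- rc$col[i]
    if (speed$speed[r, c] > 0) { cells[i, ] <- c(r, c); next }
    best <- NULL; best_d <- Inf
    for (dr in -max_snap:max_snap) for (dc in -max_snap:max_snap) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > g$n_rows || cc < 1 || cc > g$n_cols) next
      if (speed$speed[rr, cc] <= 0) next
      d <- dr * dr + dc * dc
      if (d < best_d) { best_d <- d; best <- c(rr, cc) }
    }
    if (is.null(best)) dropped <- dropped + 1L else cells[i, ] <- best
  }
  if (dropped > 0)
    warning(dropped, " facility(ies) on barrier cells with no passable ",
            "neighbour within ", max_snap, " cells dropped")
  cells <- cells[!is.na(cells[, 1]), , drop = FALSE]
  if (nrow(cells) == 0)
    stop("no usable source cells: every facility is outside the grid or ",
         "stranded on barrier cells")
  cells
}

#' Accumulate least-cost travel time from a facility set
#'
#' Multi-source Dijkstra over the gridded speed surface: every cell gets
#' the minimum travel time (minutes) to its nearest source facility.
#' Moves connect each cell to its 8 neighbours (or 16, adding knight
#' moves, which reduces octile anisotropy) with cost
#' `d * (0.5/v_from + 0.5/v_to)` — each half of the move is traversed at
#' that cell's regime. Pedestrian cells have their speed multiplied by the
#' normalized Tobler factor of the move's signed slope (see
#' [slope_factor()]); motorized cells ignore slope. Water/barrier cells
#' (speed 0) are impassable; cells with no passable route are `NA`
#' (unreachable). With symmetric per-move costs the surface is identical
#' in the population-to-facility and facility-to-population directions.
#'
#' @param speed a `speed_raster` from [build_speed_raster()].
#' @param dem elevation [acc_raster()] on the same grid, or `NULL` for
#'   flat terrain.
#' @param sources a `facility_registry` with at least one facility inside
#'   the grid. Facilities on barrier cells snap to the nearest passable
#'   cell within 3 cells, else are dropped with a warning.
#' @param connectivity 8 (queen) or 16 (queen + knight moves).
#' @param stratum,scenario metadata labels recorded on the result.
#' @return an [acc_raster()] of minutes (0 at sources, `NA` unreachable)
#'   with attributes `stratum`, `scenario`, `connectivity`.
#' @export
accumulate <- function(speed, dem = NULL, sources, connectivity = 8,
                       stratum = "all", scenario = speed$scenario) {
  g <- speed$grid
  if (is.null(dem)) {
    dem_m <- matrix(0, g$n_rows, g$n_cols)
  } else {
    check_same_grid(speed$grid, dem)
    dem_m <- dem$values
    if (any(!is.finite(dem_m))) stop("DEM has non-finite cells")
  }
  cells <- snap_sources(speed, sources)
  lin0 <- (cells[, 2] - 1L) * g$n_rows + (cells[, 1] - 1L)  # 0-based
  secs <- grid_dijkstra(speed$speed, speed$is_walking, dem_m,
                        as.integer(lin0), g$cell_size,
                        as.integer(connectivity))
  mins <- secs / 60
  mins[!is.finite(mins)] <- NA
  out <- acc_raster(g, mins, layer = "travel_time_min")
  attr(out, "stratum") <- stratum
  attr(out, "scenario") <- scenario
  attr(out, "connectivity") <- connectivity
  out
}

#' Run the full stratum-by-scenario travel-time design
#'
#' One travel-time surface per (facility stratum, speed scenario) pair —
#' twelve surfaces for the full four-strata, three-scenario design.
#'
#' @param road_raster class-code raster from [rasterize_roads()].
#' @param landcover land-cover [acc_raster()].
#' @param dem elevation [acc_raster()] or `NULL`.
#' @param table a `speed_table`.
#' @param registry a `facility_registry`.
#' @param strata character vector of strata (see [select_stratum()]).
#' @param scenarios character vector of scenarios.
#' @param connectivity 8 or 16.
#' @return named list of travel-time rasters keyed `"stratum|scenario"`.
#' @export
run_matrix <- function(road_raster, landcover, dem, table, registry,
                       strata = FACILITY_STRATA, scenarios = SCENARIOS,
                       connectivity = 8) {
  if (!length(strata) || !length(scenarios))
    stop("strata and scenarios must be non-empty")
  out <- list()
  for (sc in scenarios) {
    sr <- build_speed_raster(road_raster, landcover, table, sc)
    for (st in strata) {
      fac <- select_stratum(registry, st)
      out[[paste(st, sc, sep = "|")]] <-
        accumulate(sr, dem, fac, connectivity, stratum = st, scenario = sc)
    }
  }
  out
}
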