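#' Assign every grid cell to a zone by its centre point
#'
#' A cell belongs to the zone containing its centre; if centres fall on a
#' shared boundary the zone with the lexicographically smallest `zone_id`
#' wins, so cells partition exactly into zones and zone aggregates add up
#' to study-area aggregates.
#'
#' @param zones a `zone_set` (typically one level, see [zones_at_level()]).
#' @param grid a [grid_spec()].
#' @return integer matrix indexing into `zones$zones` (`NA` = no zone).
#' @export
zone_membership <- function(zones, grid) {
  cc <- cell_centers(grid)
  pts <- cbind(cc$x, cc$y)
  idx <- rep(NA_integer_, nrow(pts))
  ord <- order(vapply(zones$zones, function(z) as.character(z$zone_id),
                      character(1)))
  for (j in ord) {
    ring <- zones$zones[[j]]$ring
    inside <- mgcv::in.out(ring, pts)
    idx[is.na(idx) & inside] <- j
  }
  matrix(idx, grid$n_rows, grid$n_cols)
}

#' Restrict a travel-time surface to populated cells
#'
#' Cells whose population is not strictly above `min_pop` become `NA`,
#' so later summaries speak only about where women actually live.
#' Idempotent.
#'
#' @param tt travel-time [acc_raster()] (minutes).
#' @param pop population [acc_raster()] (WoCBA counts) on the same grid.
#' @param min_pop retain cells with count strictly greater than this
#'   (default 0: drop exactly the zero-population cells).
#' @return the masked travel-time raster (metadata attributes preserved).
#' @export
mask_populated <- function(tt, pop, min_pop = 0) {
  check_same_grid(tt, pop)
  v <- tt$values
  v[!(pop$values > min_pop) | is.na(pop$values)] <- NA
  out <- acc_raster(tt$grid, v, layer = tt$layer)
  for (a in c("stratum", "scenario", "connectivity"))
    attr(out, a) <- attr(tt, a)
  out
}

tt_meta <- function(tt) {
  list(stratum = attr(tt, "stratum") %||% NA_character_,
       scenario = attr(tt, "scenario") %||% NA_character_)
}

#' Zonal summaries of travel time
#'
#' Per zone: unweighted mean/min/max travel time over populated,
#' reachable cells (the area-style statistic), plus a population-weighted
#' mean column (`wmean_tt`) since zone-level planning sometimes wants the
#' person-average instead. Zones without contributing cells get
#' `n_cells = 0` and `NA` statistics.
#'
#' @param tt travel-time [acc_raster()] (minutes).
#' @param zones a `zone_set`.
#' @param pop population [acc_raster()] on the same grid.
#' @return data.frame: zone_id, zone_level, stratum, scenario, mean_tt,
#'   min_tt, max_tt, wmean_tt, n_cells.
#' @export
zonal_stats <- function(tt, zones, pop) {
  check_same_grid(tt, pop)
  meta <- tt_meta(tt)
  out <- list()
  for (lv in unique(vapply(zones$zones, function(z) z$zone_level,
                           character(1)))) {
    zl <- zones_at_level(zones, lv)
    memb <- zone_membership(zl, tt$grid)
    for (j in seq_along(zl$zones)) {
      use <- !is.na(memb) & memb == j & !is.na(tt$values) &
        !is.na(pop$values) & pop$values > 0
      v <- tt$values[use]; w <- pop$values[use]
      out[[length(out) + 1L]] <- data.frame(
        zone_id = zl$zones[[j]]$zone_id, zone_level = lv,
        stratum = meta$stratum, scenario = meta$scenario,
        mean_tt = if (length(v)) mean(v) else NA_real_,
        min_tt = if (length(v)) min(v) else NA_real_,
        max_tt = if (length(v)) max(v) else NA_real_,
        wmean_tt = if (length(v)) sum(v * w) / sum(w) else NA_real_,
        n_cells = length(v))
    }
  }
  do.call(rbind, out)
}

#' Population coverage within travel-time thresholds
#'
#' Per zone and threshold T: the percentage of WoCBA living in cells with
#' travel time at most T. Unreachable populated cells stay in the
#' denominator — coverage is a claim about all women in the zone, not
#' only those with a route. Zones with zero population get `NA`
#' percentages (undefined, not 0).
#'
#' @param tt travel-time [acc_raster()] (minutes).
#' @param pop population [acc_raster()] on the same grid.
#' @param zones a `zone_set`.
#' @param thresholds positive, sorted travel-time cutoffs in minutes.
#' @return data.frame: zone_id, zone_level, stratum, scenario, threshold,
#'   pct_wocba, wocba_covered, wocba_total.
#' @export
coverage <- function(tt, pop, zones, thresholds = c(30, 60, 120)) {
  check_same_grid(tt, pop)
  if (any(thresholds <= 0) || is.unsorted(thresholds))
    stop("thresholds must be positive and sorted ascending")
  meta <- tt_meta(tt)
  out <- list()
  for (lv in unique(vapply(zones$zones, function(z) z$zone_level,
                           character(1)))) {
    zl <- zones_at_level(zones, lv)
    memb <- zone_membership(zl, tt$grid)
    for (j in seq_along(zl$zones)) {
      inz <- !is.na(memb) & memb == j & !is.na(pop$values)
      total <- sum(pop$values[inz])
      for (th in thresholds) {
        cov <- sum(pop$values[inz & !is.na(tt$values) & tt$values <= th])
        out[[length(out) + 1L]] <- data.frame(
          zone_id = zl$zones[[j]]$zone_id, zone_level = lv,
          stratum = meta$stratum, scenario = meta$scenario, threshold = th,
          pct_wocba = if (total > 0) 100 * cov / total else NA_real_,
          wocba_covered = cov, wocba_total = total)
      }
    }
  }
  do.call(rbind, out)
}
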