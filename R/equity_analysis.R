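#' Match each grid cell to its nearest wealth-index point
#'
#' Every cell takes the RWI value of the nearest sample point (Euclidean
#' distance from the cell centre; ties go to the lowest point index).
#' No interpolation or kriging — the cell inherits the nearest estimate
#' as-is, which keeps the matching honest about the sparse RWI sampling.
#'
#' @param tt travel-time [acc_raster()] (supplies the grid; values not
#'   used).
#' @param rwi data.frame with `x`, `y`, `rwi` (>= 1 point).
#' @return an [acc_raster()] of matched RWI values.
#' @export
match_rwi <- function(tt, rwi) {
  if (is.null(rwi) || nrow(rwi) == 0) stop("RWI point set is empty")
  g <- tt$grid
  cc <- cell_centers(g)
  best <- rep(Inf, nrow(cc))
  val <- rep(NA_real_, nrow(cc))
  for (i in seq_len(nrow(rwi))) {  # ascending index: first minimum wins ties
    d2 <- (cc$x - rwi$x[i])^2 + (cc$y - rwi$y[i])^2
    better <- d2 < best
    best[better] <- d2[better]
    val[better] <- rwi$rwi[i]
  }
  acc_raster(g, matrix(val, g$n_rows, g$n_cols), layer = "rwi")
}

#' Population-weighted wealth quintiles
#'
#' Cells are sorted by wealth value ascending and cut into five groups of
#' (as nearly as possible) equal total population weight, so each
#' quintile represents one fifth of women, not one fifth of cells. A cell
#' straddling a quintile boundary is assigned to the quintile containing
#' its cumulative-weight midpoint. Equal wealth values stay contiguous in
#' the sort, and assignment is invariant to the input cell order.
#'
#' @param values wealth values per cell (vector or matrix; `NA` skipped).
#' @param weights population weights per cell, same shape; total must be
#'   positive. Cells with zero/`NA` weight get `NA` quintile.
#' @return object of class `quintile_assignment`: list with `quintile`
#'   (1 = poorest ... 5 = richest, same shape as input), `values`,
#'   `weights`.
#' @export
assign_quintiles <- function(values, weights) {
  shape <- dim(values)
  v <- as.vector(values); w <- as.vector(weights)
  if (length(v) != length(w)) stop("values and weights differ in length")
  use <- which(!is.na(v) & !is.na(w) & w > 0)
  if (!length(use) || sum(w[use]) <= 0)
    stop("total population weight must be positive")
  ord <- use[order(v[use])]            # stable: rwi ties stay contiguous
  cw <- cumsum(w[ord])
  total <- cw[length(cw)]
  mid <- cw - w[ord] / 2               # cumulative-weight midpoint per cell
  q <- clamp(ceiling(mid / (total / 5)), 1, 5)
  out <- rep(NA_integer_, length(v))
  out[ord] <- as.integer(q)
  if (!is.null(shape)) dim(out) <- shape
  structure(list(quintile = out, values = values, weights = weights),
            class = "quintile_assignment")
}

weighted_median <- function(v, w) {
  o <- order(v)
  cw <- cumsum(w[o])
  v[o][which(cw >= cw[length(cw)] / 2)[1]]
}

#' Equiplot summary: travel time by wealth quintile and zone
#'
#' For the study area and each zone at the requested level(s), the
#' population-weighted mean (and median) travel time of each wealth
#' quintile — the numbers behind an equiplot, where a wide quintile
#' spread flags wealth-related inequality in access.
#'
#' @param tt travel-time [acc_raster()] (minutes).
#' @param assignment a `quintile_assignment` from [assign_quintiles()]
#'   on the same grid.
#' @param zones a `zone_set`, typically restricted to the departement
#'   level plus the study area.
#' @return data.frame: zone_id, zone_level, stratum, scenario, quintile,
#'   mean_tt, median_tt, wocba (`NA` rows where a quintile is empty in a
#'   zone).
#' @export
equiplot_table <- function(tt, assignment, zones) {
  meta <- tt_meta(tt)
  qm <- assignment$quintile
  wm <- assignment$weights
  if (!all(dim(qm) == dim(tt$values)))
    stop("assignment and travel-time surface are on different grids")
  out <- list()
  for (lv in unique(vapply(zones$zones, function(z) z$zone_level,
                           character(1)))) {
    zl <- zones_at_level(zones, lv)
    memb <- zone_membership(zl, tt$grid)
    for (j in seq_along(zl$zones)) {
      for (q in 1:5) {
        use <- !is.na(memb) & memb == j & !is.na(qm) & qm == q &
          !is.na(tt$values)
        v <- tt$values[use]; w <- wm[use]
        out[[length(out) + 1L]] <- data.frame(
          zone_id = zl$zones[[j]]$zone_id, zone_level = lv,
          stratum = meta$stratum, scenario = meta$scenario, quintile = q,
          mean_tt = if (length(v)) sum(v * w) / sum(w) else NA_real_,
          median_tt = if (length(v)) weighted_median(v, w) else NA_real_,
          wocba = sum(w))
      }
    }
  }
  do.call(rbind, out)
}

#' Travel time along the urbanicity gradient
#'
#' Population-weighted mean travel time per urbanicity band, from the
#' densest settlement core to near-uninhabited periphery. Every band
#' present in the raster appears once; bands with no populated reachable
#' cells get `NA`.
#'
#' @param tt travel-time [acc_raster()] (minutes).
#' @param urbanicity band-code [acc_raster()] (ordinal, higher = denser;
#'   optional `bands` attribute supplies names).
#' @param pop population [acc_raster()] on the same grid.
#' @return data.frame: band, band_name, stratum, scenario, mean_tt, wocba.
#' @export
urbanicity_summary <- function(tt, urbanicity, pop) {
  check_same_grid(tt, urbanicity, pop)
  meta <- tt_meta(tt)
  bands <- sort(unique(as.vector(urbanicity$values)))
  bands <- bands[!is.na(bands)]
  nm <- attr(urbanicity, "bands")
  out <- list()
  for (b in bands) {
    use <- !is.na(urbanicity$values) & urbanicity$values == b &
      !is.na(tt$values) & !is.na(pop$values) & pop$values > 0
    v <- tt$values[use]; w <- pop$values[use]
    out[[length(out) + 1L]] <- data.frame(
      band = b,
      band_name = if (!is.null(nm) && b >= 1 && b <= length(nm)) nm[b]
      else as.character(b),
      stratum = meta$stratum, scenario = meta$scenario,
      mean_tt = if (length(v)) sum(v * w) / sum(w) else NA_real_,
      wocba = sum(w))
  }
  do.call(rbind, out)
}

#' Draw an equiplot from an equiplot table
#'
#' One horizontal row per zone, one dot per wealth quintile; the spread
#' between the poorest and richest dots visualizes the inequality gap.
#' Requires ggplot2.
#'
#' @param eq data.frame from [equiplot_table()].
#' @return a ggplot object.
#' @export
plot_equiplot <- function(eq) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  eq <- eq[!is.na(eq$mean_tt), , drop = FALSE]
  ggplot2::ggplot(eq, ggplot2::aes(x = mean_tt, y = zone_id)) +
    ggplot2::geom_line(ggplot2::aes(group = zone_id), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(quintile)), size = 3) +
    ggplot2::scale_colour_viridis_d(name = "Wealth quintile\n(1 = poorest)") +
    ggplot2::labs(x = "Mean travel time (minutes)", y = NULL) +
    ggplot2::theme_minimal()
}
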