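#' Grid geometry shared by all rasters in an analysis
#'
#' A `grid_spec` fixes the geometry every raster layer in one analysis must
#' share: number of rows and columns, square cell size in metres, and the
#' planar coordinates of the lower-left corner. Row 1 is the top row of the
#' grid (raster convention); the y axis increases northwards.
#'
#' All coordinates are planar metres. Real-data use expects inputs already
#' projected to an equal-area or UTM CRS; synthetic landscapes are generated
#' directly in planar metres so cell-distance arithmetic is exact.
#'
#' @param n_rows,n_cols grid dimensions, each at least 1.
#' @param cell_size square cell edge in metres (default 30, the resolution
#'   at which facility access is typically modelled).
#' @param origin_x,origin_y planar coordinates (metres) of the lower-left
#'   corner of the grid extent.
#' @param nodata sentinel written to file for missing cells; in memory
#'   missing cells are `NA`.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 30, origin_x = 0,
                      origin_y = 0, nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, is.finite(nodata))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = as.numeric(cell_size),
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 nodata = as.numeric(nodata)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %gm, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Construct a raster layer on a grid
#'
#' Thin container pairing a numeric matrix (`n_rows` x `n_cols`, `NA` =
#' nodata) with its [grid_spec()]. All layers of one analysis must share an
#' identical spec; [check_same_grid()] enforces this at module boundaries.
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix of dim `n_rows` x `n_cols`, or a single
#'   value recycled to the full grid.
#' @param layer optional name describing the layer (e.g. "dem", "wocba").
#' @return an object of class `acc_raster`.
#' @export
acc_raster <- function(grid, values, layer = "layer") {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(values, grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values must be a ", grid$n_rows, " x ", grid$n_cols, " matrix")
  structure(list(grid = grid, values = values, layer = layer),
            class = "acc_raster")
}

#' @export
print.acc_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<acc_raster '%s'> %d x %d @ %gm; range [%g, %g], %d NA\n",
              x$layer, x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n_rows", "n_cols", "cell_size",
                                "origin_x", "origin_y")],
                   unclass(b)[c("n_rows", "n_cols", "cell_size",
                                "origin_x", "origin_y")]))
}

#' Assert that raster layers share one grid geometry
#'
#' @param ... rasters (`acc_raster`) or bare `grid_spec` objects.
#' @return the common `grid_spec`, invisibly; errors describing both grids
#'   on the first mismatch.
#' @export
check_same_grid <- function(...) {
  objs <- list(...)
  specs <- lapply(objs, function(o) if (inherits(o, "grid_spec")) o else o$grid)
  ref <- specs[[1L]]
  for (s in specs[-1L]) {
    if (!grids_equal(ref, s))
      stop("grid mismatch: ",
           sprintf("%dx%d @%gm origin(%g,%g)", ref$n_rows, ref$n_cols,
                   ref$cell_size, ref$origin_x, ref$origin_y),
           " vs ",
           sprintf("%dx%d @%gm origin(%g,%g)", s$n_rows, s$n_cols,
                   s$cell_size, s$origin_x, s$origin_y))
  }
  invisible(ref)
}

#' Cell centre coordinates
#'
#' @param grid a [grid_spec()].
#' @return data.frame with columns `row`, `col`, `x`, `y`, one row per cell
#'   in column-major order (matching `as.vector` of the value matrix).
#' @export
cell_centers <- function(grid) {
  row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  data.frame(row = row, col = col,
             x = grid$origin_x + (col - 0.5) * grid$cell_size,
             y = grid$origin_y + (grid$n_rows - row + 0.5) * grid$cell_size)
}

#' Map planar coordinates to grid cells
#'
#' Points on the extent boundary are pulled into the edge cell so that
#' features generated exactly on the border still land on the grid.
#'
#' @param grid a [grid_spec()].
#' @param x,y numeric vectors of planar coordinates (metres).
#' @return data.frame with `row`, `col` (`NA` outside the extent).
#' @export
xy_to_cell <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- floor((x - grid$origin_x) / cs) + 1
  rfb <- floor((y - grid$origin_y) / cs) + 1   # row counted from bottom
  col[x == grid$origin_x + grid$n_cols * cs] <- grid$n_cols
  rfb[y == grid$origin_y + grid$n_rows * cs] <- grid$n_rows
  row <- grid$n_rows - rfb + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Grid extent as (xmin, ymin, xmax, ymax)
#' @param grid a [grid_spec()].
#' @return named numeric vector.
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$origin_x, ymin = grid$origin_y,
    xmax = grid$origin_x + grid$n_cols * grid$cell_size,
    ymax = grid$origin_y + grid$n_rows * grid$cell_size)
}
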