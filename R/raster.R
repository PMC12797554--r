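#' Planar raster grid
#'
#' A minimal axis-aligned raster container used throughout the package for
#' canopy height models (m), biomass surfaces (Mg/ha) and integer label maps
#' (stratum / domain codes). The grid lives in a planar coordinate system
#' with the origin at the lower-left corner; column `c` has x-centre
#' `x0 + (c - 0.5) * cell_size` and row `r` has y-centre
#' `y0 + (r - 0.5) * cell_size`, i.e. row 1 is the southernmost row.
#'
#' @param values numeric matrix of cell values, `[n_rows, n_cols]`, row 1 =
#'   south. Integer label rasters are stored as numeric with whole values.
#' @param cell_size cell side length, m (> 0).
#' @param origin length-2 numeric, (x0, y0) of the lower-left corner, m.
#' @param nodata value marking missing cells (default `NA`).
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin = c(0, 0), nodata = NA_real_) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be length-2 numeric (x0, y0)")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = nodata),
    class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %d rows x %d cols @ %g m, origin (%g, %g)\n",
              d[1L], d[2L], x$cell_size, x$origin[1L], x$origin[2L]))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: [%g, %g], mean %g\n", min(v), max(v), mean(v)))
  invisible(x)
}

#' Grid extent
#'
#' @param x a `raster_grid`.
#' @return named numeric: xmin, xmax, ymin, ymax (m).
#' @export
rg_extent <- function(x) {
  stopifnot(inherits(x, "raster_grid"))
  d <- dim(x$values)
  c(xmin = x$origin[1L], xmax = x$origin[1L] + d[2L] * x$cell_size,
    ymin = x$origin[2L], ymax = x$origin[2L] + d[1L] * x$cell_size)
}

#' x-coordinates of cell centres (west to east)
#' @param x a `raster_grid`.
#' @export
rg_xcenters <- function(x) {
  x$origin[1L] + (seq_len(ncol(x$values)) - 0.5) * x$cell_size
}

#' y-coordinates of cell centres (south to north, row 1 first)
#' @param x a `raster_grid`.
#' @export
rg_ycenters <- function(x) {
  x$origin[2L] + (seq_len(nrow(x$values)) - 0.5) * x$cell_size
}

#' Check that two rasters share the same grid geometry
#'
#' Same origin, cell size and shape. Used as a guard before any zonal or
#' cell-wise operation; mismatched grids are a hard error, never silently
#' resampled.
#'
#' @param a,b `raster_grid` objects.
#' @param what label used in the error message.
#' @return invisibly `TRUE`; errors on mismatch.
#' @export
assert_same_grid <- function(a, b, what = "rasters") {
  stopifnot(inherits(a, "raster_grid"), inherits(b, "raster_grid"))
  if (!isTRUE(all.equal(a$origin, b$origin)) ||
      a$cell_size != b$cell_size ||
      !identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s are not co-registered (origin/cell size/shape differ)",
                 what))
  invisible(TRUE)
}

#' Row/column of the cell containing a point
#'
#' @param x a `raster_grid`.
#' @param px,py point coordinates, m.
#' @return integer vector (row, col); errors if the point is off-grid.
#' @keywords internal
rg_cell_at <- function(x, px, py) {
  e <- rg_extent(x)
  if (px < e["xmin"] || px >= e["xmax"] || py < e["ymin"] || py >= e["ymax"])
    stop(sprintf("point (%g, %g) is outside the raster extent", px, py))
  r <- as.integer(floor((py - x$origin[2L]) / x$cell_size)) + 1L
  c <- as.integer(floor((px - x$origin[1L]) / x$cell_size)) + 1L
  c(r, c)
}
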