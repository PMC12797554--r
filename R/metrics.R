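#' @title Area-based canopy metrics
#' @description Canopy metrics in the area-based tradition of lidar forest
#'   inventory, computed from a fine canopy height model for circular plot
#'   footprints and for square windows at coarser resolutions.
#'
#'   Conventions (fixed for bit-reproducibility):
#'   * height percentiles `h10, h20, h25, h30, h40, h50, h99` are computed
#'     over cells at least 2 m tall (the vegetation-return convention),
#'     with linear interpolation between order statistics (quantile type 7);
#'     if no cell reaches 2 m all percentiles are 0;
#'   * `h_mean` is the mean over ALL cells (so the mean aggregates linearly
#'     across nested windows, unlike every percentile);
#'   * `fc` is the fraction of cells >= 2 m (the model predictor), `fc4` the
#'     fraction >= 4 m (the plot-retention filter).
#' @name canopy-metrics
NULL

METRIC_PERCENTILES <- c(10, 20, 25, 30, 40, 50, 99)
METRIC_NAMES <- c(paste0("h", METRIC_PERCENTILES), "h_mean", "fc", "fc4")
VEG_HEIGHT_M <- 2

# Percentile with linear interpolation (type 7) over the vegetation cells of
# each column of a cells-by-windows matrix. Returns length-ncol vector.
col_veg_percentile <- function(sorted_asc, n_veg, p) {
  nw <- ncol(sorted_asc)
  out <- numeric(nw)
  pos <- which(n_veg > 0L)
  if (!length(pos)) return(out)
  idx <- (n_veg[pos] - 1) * p / 100 + 1
  lo <- floor(idx)
  hi <- ceiling(idx)
  frac <- idx - lo
  vlo <- sorted_asc[cbind(lo, pos)]
  vhi <- sorted_asc[cbind(hi, pos)]
  out[pos] <- vlo * (1 - frac) + vhi * frac
  out
}

# All metrics for a cells-by-windows value matrix (columns = windows).
metric_block <- function(vals) {
  n_veg <- colSums(vals >= VEG_HEIGHT_M)
  masked <- vals
  masked[vals < VEG_HEIGHT_M] <- Inf   # push sub-canopy cells past the end
  sorted <- apply(masked, 2L, sort)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = 1L)
  out <- list()
  for (p in METRIC_PERCENTILES)
    out[[paste0("h", p)]] <- col_veg_percentile(sorted, n_veg, p)
  out$h_mean <- colMeans(vals)
  out$fc <- colMeans(vals >= VEG_HEIGHT_M)
  out$fc4 <- colMeans(vals >= 4)
  out
}

#' Canopy metrics for one circular plot footprint
#'
#' @param chm fine-resolution canopy height [raster_grid()].
#' @param center length-2 numeric (x, y) of the plot centre, m.
#' @param radius_m plot radius, m; the footprint (cells whose centres fall in
#'   the circle) must lie fully inside the raster unless `clip = TRUE`.
#' @param plot_id used in error messages only.
#' @param clip if `TRUE`, footprints crossing the raster boundary are clipped
#'   to in-raster cells (the convention for systematic samples whose grid
#'   runs to the edge) instead of erroring.
#' @return named numeric: h10...h99, h_mean, fc, fc4, n_cells.
#' @export
plot_metrics <- function(chm, center, radius_m, plot_id = NA, clip = FALSE) {
  stopifnot(inherits(chm, "raster_grid"))
  ext <- rg_extent(chm)
  if (!clip &&
      (center[1L] - radius_m < ext["xmin"] || center[1L] + radius_m > ext["xmax"] ||
       center[2L] - radius_m < ext["ymin"] || center[2L] + radius_m > ext["ymax"]))
    stop("plot ", plot_id, ": footprint extends outside the raster")
  if (center[1L] < ext["xmin"] || center[1L] >= ext["xmax"] ||
      center[2L] < ext["ymin"] || center[2L] >= ext["ymax"])
    stop("plot ", plot_id, ": centre outside the raster")
  cells <- footprint_cells(chm, center[1L], center[2L], radius_m)
  vals <- matrix(chm$values[cells], ncol = 1L)
  m <- metric_block(vals)
  c(vapply(m, function(v) v[1L], numeric(1)), n_cells = length(cells))
}

#' Append footprint metrics to a plot table
#'
#' Adds the columns `h10...h99, h_mean, fc, fc4` (see [plot_metrics()]) to a
#' plot table, computed over each plot's circular footprint.
#'
#' @param plots plot table from [sample_nfi_plots()].
#' @param chm fine canopy height [raster_grid()].
#' @param radius_m plot radius, m.
#' @return the plot table with metric columns appended.
#' @export
add_plot_metrics <- function(plots, chm, radius_m = 25) {
  mm <- matrix(0, nrow(plots), length(METRIC_NAMES),
               dimnames = list(NULL, METRIC_NAMES))
  for (i in seq_len(nrow(plots))) {
    m <- plot_metrics(chm, c(plots$x[i], plots$y[i]), radius_m,
                      plot_id = plots$plot_id[i], clip = TRUE)
    mm[i, ] <- m[METRIC_NAMES]
  }
  cbind(plots, as.data.frame(mm))
}

#' Canopy metrics on a square window grid
#'
#' Tiles the landscape with square windows of side `resolution_m` and applies
#' the same metric definitions as [plot_metrics()] to each window. Partial
#' windows at the east/north edges are dropped. The window grid keeps the
#' fine raster's origin.
#'
#' @param chm fine canopy height [raster_grid()].
#' @param resolution_m window side, m; must be an integer multiple of the
#'   fine cell size.
#' @param metrics which metrics to compute (default all); restricting the
#'   set skips the per-window sort when no percentile is requested.
#' @return object of class `metric_grid`: `$resolution_m` plus `$grids`, a
#'   named list of co-registered [raster_grid()]s, one per metric.
#' @export
window_metrics <- function(chm, resolution_m, metrics = METRIC_NAMES) {
  stopifnot(inherits(chm, "raster_grid"))
  cs <- chm$cell_size
  k <- resolution_m / cs
  if (resolution_m < cs || abs(k - round(k)) > 1e-9)
    stop("resolution ", resolution_m, " m is not representable on the ",
         cs, "-m fine grid")
  k <- as.integer(round(k))
  metrics <- match.arg(metrics, METRIC_NAMES, several.ok = TRUE)
  d <- dim(chm$values)
  nwr <- d[1L] %/% k
  nwc <- d[2L] %/% k
  if (nwr == 0L || nwc == 0L)
    stop("resolution ", resolution_m, " m exceeds the raster extent")
  b <- window_blocks(chm$values, k, nwr, nwc)

  need_pct <- any(grepl("^h[0-9]", metrics))
  vals <- list()
  if (need_pct) {
    mb <- metric_block(b)
    vals <- mb[metrics]
  } else {
    if ("h_mean" %in% metrics) vals$h_mean <- colMeans(b)
    if ("fc" %in% metrics) vals$fc <- colMeans(b >= VEG_HEIGHT_M)
    if ("fc4" %in% metrics) vals$fc4 <- colMeans(b >= 4)
  }
  grids <- lapply(vals, function(v)
    raster_grid(matrix(v, nwr, nwc), resolution_m, origin = chm$origin))
  structure(list(resolution_m = resolution_m, grids = grids[metrics]),
            class = "metric_grid")
}

# Rearrange the trimmed fine matrix into a (k*k) x (nwr*nwc) matrix whose
# columns are the k-by-k windows, window (wr, wc) in column (wc-1)*nwr + wr.
window_blocks <- function(m, k, nwr, nwc) {
  m <- m[seq_len(nwr * k), seq_len(nwc * k), drop = FALSE]
  dim(m) <- c(k, nwr, k, nwc)
  m <- aperm(m, c(1L, 3L, 2L, 4L))
  dim(m) <- c(k * k, nwr * nwc)
  m
}

#' Stamp majority stratum/domain labels onto a metric grid
#'
#' Each window receives the majority label of the fine cells it covers; ties
#' are broken toward the smallest code.
#'
#' @param metric_grid a [window_metrics()] result.
#' @param strata,domains fine label [raster_grid()]s co-registered with the
#'   CHM the metric grid was built from.
#' @return the metric grid with `$strata` and `$domains` label
#'   [raster_grid()]s added.
#' @export
stamp_labels <- function(metric_grid, strata, domains) {
  stopifnot(inherits(metric_grid, "metric_grid"))
  ref <- metric_grid$grids[[1L]]
  k <- as.integer(round(metric_grid$resolution_m / strata$cell_size))
  nwr <- nrow(ref$values)
  nwc <- ncol(ref$values)
  majority <- function(lab_m) {
    b <- window_blocks(lab_m, k, nwr, nwc)
    v <- apply(b, 2L, function(col) {
      u <- sort(unique(col))
      u[which.max(tabulate(match(col, u)))]
    })
    raster_grid(matrix(v, nwr, nwc), metric_grid$resolution_m,
                origin = ref$origin)
  }
  metric_grid$strata <- majority(strata$values)
  metric_grid$domains <- majority(domains$values)
  metric_grid
}

#' Metric grid as a window-level data frame
#'
#' One row per window, columns = metrics (+ stratum/domain when stamped).
#'
#' @param metric_grid a [window_metrics()] result.
#' @return data.frame.
#' @export
metric_grid_df <- function(metric_grid) {
  stopifnot(inherits(metric_grid, "metric_grid"))
  out <- as.data.frame(lapply(metric_grid$grids, function(g)
    as.vector(g$values)))
  if (!is.null(metric_grid$strata)) {
    out$stratum <- as.vector(metric_grid$strata$values)
    out$domain <- as.vector(metric_grid$domains$values)
  }
  out
}
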