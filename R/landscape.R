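#' Landscape generator configuration
#'
#' Describes the synthetic world the pipeline is tested against: a
#' multi-stratum forest landscape with a spatially autocorrelated canopy
#' height model (CHM), canopy gaps, a per-stratum power-law height-to-biomass
#' link, and a national-inventory-style systematic plot design (1-km grid of
#' 25-m-radius circular plots, retained only where canopy cover at a 4-m
#' threshold reaches 10%).
#'
#' Per-stratum vectors are recycled to `n_strata` if scalar. Defaults portray
#' a heterogeneous mixed Mediterranean/temperate mosaic: right-skewed canopy
#' heights (CV 0.45), patchy gaps, biomass exponents near 1.5 and ~30%
#' relative plot measurement error (the magnitude typical of area-based
#' biomass calibrations).
#'
#' @param extent_m landscape width and height, m (each divisible by 100 and
#'   by `fine_cell_m`).
#' @param fine_cell_m fine CHM resolution, m.
#' @param n_strata,n_domains number of forest strata / administrative domains.
#' @param mean_height_m per-stratum mean canopy height, m.
#' @param height_cv per-stratum coefficient of variation of height.
#' @param correlation_range_m per-stratum practical correlation range of the
#'   height field, m (lag at which the semivariogram reaches ~95% of sill).
#' @param gap_fraction per-stratum proportion of cells forced to height 0
#'   (canopy gaps), in [0, 1).
#' @param biomass_a0,biomass_b0 per-stratum generative power-law
#'   `AGBD = a0 * h^b0` (Mg/ha with h in m).
#' @param noise_sdlog sd of the mean-one multiplicative lognormal measurement
#'   noise applied to plot-scale biomass.
#' @param plot_spacing_m,plot_radius_m systematic plot grid spacing and plot
#'   radius, m (`plot_radius_m < plot_spacing_m / 2`).
#' @param cover_min,cover_height_m plot retention rule: keep a plot if the
#'   fraction of footprint cells with height >= `cover_height_m` is at least
#'   `cover_min`.
#' @param patches_per_stratum seed points per stratum for the nearest-seed
#'   tessellation that lays out stratum patches.
#' @param seed RNG seed; identical seeds give bit-identical landscapes.
#' @return object of class `landscape_config`.
#' @export
landscape_config <- function(extent_m = c(6000, 6000),
                             fine_cell_m = 2,
                             n_strata = 6,
                             n_domains = 10,
                             mean_height_m = c(12, 10, 7, 11, 14, 8),
                             height_cv = 0.45,
                             correlation_range_m = 150,
                             gap_fraction = c(0.30, 0.25, 0.35, 0.25, 0.15, 0.35),
                             biomass_a0 = c(1.9, 2.2, 1.6, 2.0, 2.4, 1.7),
                             biomass_b0 = c(1.50, 1.45, 1.60, 1.50, 1.40, 1.55),
                             noise_sdlog = 0.3,
                             plot_spacing_m = 1000,
                             plot_radius_m = 25,
                             cover_min = 0.10,
                             cover_height_m = 4,
                             patches_per_stratum = 3,
                             seed = 1L) {
  if (length(extent_m) == 1L) extent_m <- rep(extent_m, 2L)
  if (any(extent_m %% 100 != 0))
    stop("extent_m must be divisible by 100 so that all metric grids nest")
  if (any(extent_m %% fine_cell_m != 0))
    stop("extent_m must be divisible by fine_cell_m")
  rec <- function(x) {
    if (length(x) == 1L) x <- rep(x, n_strata)
    if (length(x) > n_strata) x <- x[seq_len(n_strata)]  # defaults shrink
    if (length(x) != n_strata)
      stop("per-stratum parameter of length ", length(x),
           " cannot be recycled to n_strata = ", n_strata)
    x
  }
  gap_fraction <- rec(gap_fraction)
  if (any(gap_fraction < 0 | gap_fraction >= 1))
    stop("gap_fraction must be in [0, 1)")
  if (plot_radius_m >= plot_spacing_m / 2)
    stop("plot_radius_m must be smaller than plot_spacing_m / 2")
  structure(list(
    extent_m = as.numeric(extent_m), fine_cell_m = fine_cell_m,
    n_strata = as.integer(n_strata), n_domains = as.integer(n_domains),
    mean_height_m = rec(mean_height_m), height_cv = rec(height_cv),
    correlation_range_m = rec(correlation_range_m),
    gap_fraction = gap_fraction,
    biomass_a0 = rec(biomass_a0), biomass_b0 = rec(biomass_b0),
    noise_sdlog = noise_sdlog,
    plot_spacing_m = plot_spacing_m, plot_radius_m = plot_radius_m,
    cover_min = cover_min, cover_height_m = cover_height_m,
    patches_per_stratum = as.integer(patches_per_stratum),
    seed = as.integer(seed)), class = "landscape_config")
}

# Stationary unit-variance Gaussian random field on a torus: white noise
# convolved with a Gaussian kernel in the frequency domain, then empirically
# standardised. The kernel sd sigma = range / (2*sqrt(3)) gives correlogram
# rho(h) = exp(-3 h^2 / range^2): rho(range) ~ 0.05, i.e. the semivariogram
# reaches ~95% of sill at the practical range.
gaussian_field <- function(n_rows, n_cols, cell_size, range_m) {
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_m <= 0) return(w)
  sigma <- range_m / (2 * sqrt(3))
  fy <- c(0:floor(n_rows / 2), -(ceiling(n_rows / 2) - 1):-1)[seq_len(n_rows)] /
    (n_rows * cell_size)
  fx <- c(0:floor(n_cols / 2), -(ceiling(n_cols / 2) - 1):-1)[seq_len(n_cols)] /
    (n_cols * cell_size)
  h <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, "+"))
  z <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / (n_rows * n_cols)
  (z - mean(z)) / stats::sd(z)
}

# Nearest-seed-point tessellation of stratum patches.
tessellate_strata <- function(xc, yc, n_strata, patches_per_stratum,
                              extent_m) {
  n_seeds <- n_strata * patches_per_stratum
  sx <- stats::runif(n_seeds, 0, extent_m[1L])
  sy <- stats::runif(n_seeds, 0, extent_m[2L])
  seed_stratum <- rep(seq_len(n_strata), each = patches_per_stratum)
  best_d2 <- matrix(Inf, length(yc), length(xc))
  lab <- matrix(0L, length(yc), length(xc))
  for (k in seq_len(n_seeds)) {
    d2 <- outer((yc - sy[k])^2, (xc - sx[k])^2, "+")
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    lab[upd] <- seed_stratum[k]
  }
  lab
}

#' Generate a synthetic forest landscape
#'
#' Builds the fine-resolution CHM, stratum and domain label rasters and the
#' per-cell biomass truth. Within each stratum, heights are a lognormal
#' transform of a stationary autocorrelated Gaussian field, moment-matched to
#' the stratum mean and CV; gap cells (an independent field thresholded at
#' the stratum gap fraction) are forced to height 0. True per-cell biomass is
#' `a0 * h^b0` (Mg/ha). Strata form contiguous nearest-seed patches; domains
#' are a rectangular tiling.
#'
#' @param config a [landscape_config()].
#' @return list with elements `chm`, `strata`, `domains` (all
#'   [raster_grid()]s), and `truth` (class `landscape_truth`: `$biomass`
#'   raster plus `$table`, the exact per-scope means/totals of
#'   [true_scope_statistics()]).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  cs <- config$fine_cell_m
  nc <- as.integer(config$extent_m[1L] / cs)
  nr <- as.integer(config$extent_m[2L] / cs)
  xc <- (seq_len(nc) - 0.5) * cs
  yc <- (seq_len(nr) - 0.5) * cs

  strata_m <- tessellate_strata(xc, yc, config$n_strata,
                                config$patches_per_stratum, config$extent_m)
  counts <- tabulate(strata_m, nbins = config$n_strata)
  if (any(counts == 0L))
    stop("degenerate stratum with zero cells: ",
         paste(which(counts == 0L), collapse = ", "),
         " (re-seed or enlarge the landscape)")

  # rectangular domain tiling, grid shape as square as the aspect allows
  nd <- config$n_domains
  divs <- which(nd %% seq_len(nd) == 0L)
  ndx <- divs[which.min(abs(divs - sqrt(nd * config$extent_m[1L] /
                                          config$extent_m[2L])))]
  ndy <- nd %/% ndx
  dcol <- pmin(ndx, floor(xc / (config$extent_m[1L] / ndx)) + 1L)
  drow <- pmin(ndy, floor(yc / (config$extent_m[2L] / ndy)) + 1L)
  domains_m <- outer(drow, dcol, function(r, c) (r - 1L) * ndx + c)
  storage.mode(domains_m) <- "double"
  storage.mode(strata_m) <- "double"

  # one standardised field per distinct correlation range, shared by strata
  ranges <- config$correlation_range_m
  fields <- lapply(unique(ranges), function(r) gaussian_field(nr, nc, cs, r))
  names(fields) <- as.character(unique(ranges))
  gap_field <- gaussian_field(nr, nc, cs, max(ranges))

  chm_m <- matrix(0, nr, nc)
  for (s in seq_len(config$n_strata)) {
    idx <- strata_m == s
    z <- fields[[as.character(ranges[s])]][idx]
    cv <- config$height_cv[s]
    if (cv > 0) {
      sg2 <- log(1 + cv^2)
      h <- exp(log(config$mean_height_m[s]) - sg2 / 2 + sqrt(sg2) * z)
    } else {
      h <- rep(config$mean_height_m[s], sum(idx))
    }
    gf <- config$gap_fraction[s]
    if (gf > 0) {
      g <- gap_field[idx]
      h[g <= stats::quantile(g, gf, type = 1)] <- 0
    }
    chm_m[idx] <- h
  }

  chm <- raster_grid(chm_m, cs)
  strata <- raster_grid(strata_m, cs)
  domains <- raster_grid(domains_m, cs)
  bio_m <- config$biomass_a0[strata_m] * chm_m^config$biomass_b0[strata_m]
  biomass <- raster_grid(bio_m, cs)
  truth <- structure(
    list(biomass = biomass,
         table = true_scope_statistics(biomass, strata, domains)),
    class = "landscape_truth")
  list(chm = chm, strata = strata, domains = domains, truth = truth,
       config = config)
}

#' Exact scope statistics of a biomass truth raster
#'
#' Aggregates the per-cell truth to exact means (Mg/ha) and totals (Mg) for
#' the whole landscape, each stratum, each domain and each stratum-by-domain
#' intersection. Validation surface for bias and confidence-interval coverage
#' tests: `total = mean * area_ha` holds exactly per scope, and scope totals
#' partition the landscape total.
#'
#' @param biomass,strata,domains co-registered [raster_grid()]s.
#' @return data.frame with columns scope_type, stratum, domain, n_cells,
#'   area_ha, true_mean, true_total.
#' @export
true_scope_statistics <- function(biomass, strata, domains) {
  assert_same_grid(biomass, strata, "biomass/strata rasters")
  assert_same_grid(biomass, domains, "biomass/domains rasters")
  b <- as.vector(biomass$values)
  s <- as.vector(strata$values)
  d <- as.vector(domains$values)
  cell_ha <- biomass$cell_size^2 / 1e4
  one <- function(scope_type, stratum, domain, vals) {
    if (length(vals) == 0L)
      stop("scope with zero cells: ", scope_type, " ", stratum, "/", domain)
    data.frame(scope_type = scope_type, stratum = stratum, domain = domain,
               n_cells = length(vals), area_ha = length(vals) * cell_ha,
               true_mean = mean(vals), true_total = sum(vals) * cell_ha)
  }
  out <- list(one("landscape", NA_real_, NA_real_, b))
  for (sv in sort(unique(s)))
    out[[length(out) + 1L]] <- one("stratum", sv, NA_real_, b[s == sv])
  for (dv in sort(unique(d)))
    out[[length(out) + 1L]] <- one("domain", NA_real_, dv, b[d == dv])
  sd_key <- interaction(s, d, drop = TRUE)
  for (k in levels(sd_key)) {
    i <- which(sd_key == k)
    out[[length(out) + 1L]] <- one("stratum_x_domain", s[i[1L]], d[i[1L]],
                                   b[i])
  }
  do.call(rbind, out)
}

# Linear cell indices of fine cells whose centres fall inside the circle.
footprint_cells <- function(grid, px, py, radius_m) {
  cs <- grid$cell_size
  if (radius_m < cs)
    stop("plot radius (", radius_m, " m) smaller than one fine cell (",
         cs, " m)")
  d <- dim(grid$values)
  xc <- rg_xcenters(grid)
  yc <- rg_ycenters(grid)
  cr <- max(1L, ceiling((px - radius_m) / cs)):min(d[2L], ceiling((px + radius_m) / cs))
  rr <- max(1L, ceiling((py - radius_m) / cs)):min(d[1L], ceiling((py + radius_m) / cs))
  inside <- outer((yc[rr] - py)^2, (xc[cr] - px)^2, "+") <= radius_m^2
  idx <- which(inside)
  (rep(cr, each = length(rr))[idx] - 1L) * d[1L] + rep(rr, length(cr))[idx]
}

#' Sample systematic inventory plots
#'
#' Lays a systematic square grid of circular plots with a seeded uniform
#' random offset, applies the canopy-cover retention rule (fraction of
#' footprint cells at least `cover_height_m` tall must reach `cover_min`),
#' and records for each retained plot the stratum/domain of its centre cell
#' and its field biomass: the mean of the truth raster over the footprint,
#' perturbed by mean-one multiplicative lognormal noise of sd `noise_sdlog`.
#'
#' The offset is drawn uniformly on `[0, spacing)` in each axis, which keeps
#' every cell's inclusion probability constant across the landscape (the
#' property design-based unbiasedness rests on). Footprints of plots near
#' the raster boundary are clipped to in-raster cells.
#'
#' @param chm,strata,domains co-registered fine [raster_grid()]s.
#' @param truth a `landscape_truth` (or a biomass [raster_grid()]).
#' @param spacing_m,radius_m plot grid spacing and plot radius, m.
#' @param cover_min,cover_height_m retention rule (see above); `cover_min = 0`
#'   retains every plot.
#' @param noise_sdlog sd of the lognormal measurement noise (0 = none).
#' @param seed optional integer; when given, sampling is reproducible on its
#'   own, independent of the surrounding RNG state.
#' @return data.frame (plot table): plot_id, x, y, stratum, domain,
#'   cover4, agbd_mg_ha. Zero rows if every plot fails the cover rule.
#' @export
sample_nfi_plots <- function(chm, strata, domains, truth,
                             spacing_m = 1000, radius_m = 25,
                             cover_min = 0.10, cover_height_m = 4,
                             noise_sdlog = 0, seed = NULL) {
  assert_same_grid(chm, strata, "chm/strata rasters")
  assert_same_grid(chm, domains, "chm/domains rasters")
  biomass <- if (inherits(truth, "landscape_truth")) truth$biomass else truth
  assert_same_grid(chm, biomass, "chm/truth rasters")
  if (spacing_m < 2 * radius_m)
    stop("spacing_m must be at least 2 * radius_m")
  if (!is.null(seed)) set.seed(seed)
  ext <- rg_extent(chm)
  ox <- stats::runif(1, 0, spacing_m)
  oy <- stats::runif(1, 0, spacing_m)
  px <- seq(ext["xmin"] + ox, ext["xmax"] - 1e-9, by = spacing_m)
  py <- seq(ext["ymin"] + oy, ext["ymax"] - 1e-9, by = spacing_m)
  centers <- expand.grid(x = px, y = py)
  n <- nrow(centers)
  noise <- if (noise_sdlog > 0)
    exp(stats::rnorm(n, -noise_sdlog^2 / 2, noise_sdlog)) else rep(1, n)

  rows <- vector("list", n)
  kept <- 0L
  for (i in seq_len(n)) {
    cells <- footprint_cells(chm, centers$x[i], centers$y[i], radius_m)
    hv <- chm$values[cells]
    if (mean(hv >= cover_height_m) < cover_min) next
    kept <- kept + 1L
    rc <- rg_cell_at(chm, centers$x[i], centers$y[i])
    rows[[kept]] <- data.frame(
      plot_id = i, x = centers$x[i], y = centers$y[i],
      stratum = strata$values[rc[1L], rc[2L]],
      domain = domains$values[rc[1L], rc[2L]],
      cover4 = mean(hv >= cover_height_m),
      agbd_mg_ha = mean(biomass$values[cells]) * noise[i])
  }
  if (kept == 0L)
    return(data.frame(plot_id = integer(), x = numeric(), y = numeric(),
                      stratum = numeric(), domain = numeric(),
                      cover4 = numeric(), agbd_mg_ha = numeric()))
  out <- do.call(rbind, rows[seq_len(kept)])
  rownames(out) <- NULL
  out
}
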