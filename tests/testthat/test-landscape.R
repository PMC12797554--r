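test_that("config invariants are enforced", {
  expect_error(landscape_config(extent_m = 1050), "divisible by 100")
  expect_error(landscape_config(extent_m = 1000, fine_cell_m = 3),
               "divisible by fine_cell_m")
  expect_error(quick_config(gap_fraction = 1), "gap_fraction")
  expect_error(landscape_config(plot_spacing_m = 40, plot_radius_m = 25),
               "plot_radius_m")
  expect_error(quick_config(mean_height_m = c(1, 2)), "recycled")
})

test_that("same seed gives bit-identical landscapes and plots", {
  a <- generate_landscape(quick_config(seed = 7))
  b <- generate_landscape(quick_config(seed = 7))
  expect_identical(a$chm$values, b$chm$values)
  expect_identical(a$strata$values, b$strata$values)
  expect_identical(a$truth$biomass$values, b$truth$biomass$values)
  pa <- sample_nfi_plots(a$chm, a$strata, a$domains, a$truth, 200, 25,
                         noise_sdlog = 0.3, seed = 11)
  pb <- sample_nfi_plots(b$chm, b$strata, b$domains, b$truth, 200, 25,
                         noise_sdlog = 0.3, seed = 11)
  expect_identical(pa, pb)
  expect_false(identical(
    a$chm$values, generate_landscape(quick_config(seed = 8))$chm$values))
})

test_that("degenerate field: CV = 0 and no gaps gives per-stratum constants", {
  ls <- generate_landscape(quick_config(height_cv = 0, gap_fraction = 0,
                                        seed = 3))
  for (s in 1:6) {
    h <- ls$chm$values[ls$strata$values == s]
    expect_equal(length(unique(h)), 1L)
    expect_equal(h[1L], ls$config$mean_height_m[s])
  }
})

test_that("gap cells are below 0.5 m at close to the requested fraction", {
  ls <- generate_landscape(quick_config(gap_fraction = 0.3, seed = 5))
  for (s in 1:6) {
    h <- ls$chm$values[ls$strata$values == s]
    expect_equal(mean(h < 0.5), 0.3, tolerance = 0.02)
  }
  expect_true(all(ls$chm$values >= 0))
})

test_that("true scope totals are exact and partition the landscape", {
  ls <- generate_landscape(quick_config(seed = 2))
  tt <- ls$truth$table
  land <- tt[tt$scope_type == "landscape", ]
  for (st in c("stratum", "domain", "stratum_x_domain")) {
    sub <- tt[tt$scope_type == st, ]
    expect_equal(sum(sub$true_total), land$true_total, tolerance = 1e-6)
    expect_equal(sum(sub$n_cells), land$n_cells)
  }
  # total = mean * area, per scope, to 1e-6 relative
  expect_equal(tt$true_total, tt$true_mean * tt$area_ha, tolerance = 1e-6)
  # hand aggregates
  expect_equal(true_scope_statistics(
    rg(c(50, 150), 1, 2), rg(c(1, 1), 1, 2), rg(c(1, 1), 1, 2)
  )$true_mean[1L], 100)
  u <- rg(rep(100, 4), 2, 2, cs = 50)  # 100 m x 100 m = 1 ha at 100 Mg/ha
  expect_equal(true_scope_statistics(u, rg(rep(1, 4), 2, 2, cs = 50),
                                     rg(rep(1, 4), 2, 2, cs = 50))$true_total[1L],
               100)
})

test_that("systematic sampling honours the grid count and the cover filter", {
  # 4 x 4 km, 1-km spacing, no cover filter: always 16 plots
  cfg <- landscape_config(extent_m = 4000, fine_cell_m = 4, seed = 9,
                          plot_spacing_m = 1000)
  ls <- generate_landscape(cfg)
  for (s in 1:3) {
    p <- sample_nfi_plots(ls$chm, ls$strata, ls$domains, ls$truth, 1000, 25,
                          cover_min = 0, seed = s)
    expect_equal(nrow(p), 16L)
  }
  # all-zero CHM: every plot fails the 10% cover rule
  zero <- raster_grid(matrix(0, 250, 250), 4)
  lab <- raster_grid(matrix(1, 250, 250), 4)
  expect_equal(nrow(sample_nfi_plots(zero, lab, lab, zero, 200, 25,
                                     cover_min = 0.10, seed = 1)), 0L)
  # plots carry the centre cell's labels and positive biomass
  p <- sample_nfi_plots(ls$chm, ls$strata, ls$domains, ls$truth, 1000, 25,
                        cover_min = 0, seed = 4)
  expect_true(all(p$stratum %in% 1:6))
  expect_true(all(p$agbd_mg_ha >= 0))
  expect_error(sample_nfi_plots(ls$chm, ls$strata, ls$domains, ls$truth,
                                1000, 2, seed = 1), "smaller than one fine cell")
  expect_error(sample_nfi_plots(ls$chm, ls$strata, ls$domains, ls$truth,
                                40, 25, seed = 1), "2 \\* radius")
})

test_that("noise-free plot means converge to stratum truth over offsets", {
  # two large contiguous strata (one boundary) so footprints straddling
  # stratum boundaries - which mix neighbouring biomass into the plot value,
  # a support effect, not a sampling bias - stay rare
  ls <- generate_landscape(landscape_config(
    extent_m = 6000, fine_cell_m = 4, n_strata = 2, patches_per_stratum = 1,
    mean_height_m = c(12, 8), biomass_a0 = c(1.9, 1.6),
    gap_fraction = c(0.2, 0.3), plot_spacing_m = 600, seed = 31))
  tt <- ls$truth$table
  acc <- list()
  for (r in 1:100) {
    p <- sample_nfi_plots(ls$chm, ls$strata, ls$domains, ls$truth, 600, 25,
                          cover_min = 0, noise_sdlog = 0, seed = 1000 + r)
    acc[[r]] <- p[, c("stratum", "agbd_mg_ha")]
  }
  pooled <- do.call(rbind, acc)
  checked <- 0L
  for (s in unique(pooled$stratum)) {
    n_s <- sum(pooled$stratum == s)
    if (n_s < 500) next   # tiny slivers are dominated by sampling noise
    truth_s <- tt$true_mean[tt$scope_type == "stratum" & tt$stratum == s]
    bias <- mean(pooled$agbd_mg_ha[pooled$stratum == s]) / truth_s - 1
    expect_lt(abs(bias), 0.02)
    checked <- checked + 1L
  }
  expect_gte(checked, 2L)
  # and the landscape-level plot mean is unbiased too
  land <- tt$true_mean[tt$scope_type == "landscape"]
  expect_lt(abs(mean(pooled$agbd_mg_ha) / land - 1), 0.02)
})

test_that("height field reaches ~95% of sill near the stated range", {
  # 4 x 4 km, range 200 m; brute-force semivariogram on a coarse subsample
  ls <- generate_landscape(landscape_config(
    extent_m = 4000, fine_cell_m = 4, n_strata = 1, n_domains = 1,
    mean_height_m = 10, height_cv = 0.45, correlation_range_m = 200,
    gap_fraction = 0, plot_spacing_m = 1000, seed = 12))
  idx <- seq(1, 1000, by = 20)            # 50 x 50 subsample
  h <- ls$chm$values[idx, idx]
  xy <- expand.grid(x = idx * 4, y = idx * 4)
  v <- as.vector(h)
  dmat <- as.matrix(stats::dist(xy))
  gsq <- outer(v, v, function(a, b) (a - b)^2) / 2
  lags <- seq(80, 600, by = 40)
  emp <- vapply(lags, function(L) {
    sel <- dmat > L - 40 & dmat <= L
    mean(gsq[sel])
  }, numeric(1))
  sill <- stats::var(v)
  # lag at which the variogram crosses 95% of sill, interpolated linearly
  # between bin midpoints
  mids <- lags - 20
  k <- which(emp >= 0.95 * sill)[1L]
  reached <- if (k == 1L) mids[1L] else
    mids[k - 1L] + (0.95 * sill - emp[k - 1L]) / (emp[k] - emp[k - 1L]) *
      (mids[k] - mids[k - 1L])
  expect_lt(abs(reached - 200) / 200, 0.25)
})
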