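# Fixtures are built in code; nothing binary ships with the package.

# Tiny raster from a vector/matrix, row 1 = south.
rg <- function(v, nr, nc, cs = 1, origin = c(0, 0)) {
  raster_grid(matrix(v, nr, nc), cs, origin = origin)
}

# Small fast landscape config for unit tests.
quick_config <- function(extent_m = 1000, fine_cell_m = 2, seed = 1L, ...) {
  landscape_config(extent_m = extent_m, fine_cell_m = fine_cell_m,
                   plot_spacing_m = 200, seed = seed, ...)
}

# Synthetic calibration plots drawn straight from a known power law
# y = a * h1^b * fc^c with mean-one lognormal noise of sd `sdlog`.
power_law_plots <- function(n, a, b, c = NULL, sdlog = 0,
                            h_meanlog = log(10), h_sdlog = 0.45) {
  h1 <- exp(rnorm(n, h_meanlog, h_sdlog))
  fc <- runif(n, 0.2, 1)
  mu <- if (is.null(c)) a * h1^b else a * h1^b * fc^c
  noise <- if (sdlog > 0) exp(rnorm(n, -sdlog^2 / 2, sdlog)) else 1
  data.frame(h1 = h1, fc = fc, agbd_mg_ha = mu * noise)
}

# Brute-force percentile oracle: sort-and-index with linear interpolation
# over the vegetation (>= 2 m) cells; independent of the package's
# vectorised path.
oracle_percentile <- function(values, p) {
  veg <- sort(values[values >= 2])
  m <- length(veg)
  if (m == 0L) return(0)
  idx <- (m - 1) * p / 100 + 1
  lo <- floor(idx)
  hi <- ceiling(idx)
  veg[lo] * (1 - (idx - lo)) + veg[hi] * (idx - lo)
}

# Hand-rolled power-model with fixed parameters and covariance, bypassing
# fitting; used where a known model is the input.
fixed_model <- function(a, b, c = NULL, covariance = NULL, predictors = NULL,
                        stratum = NA) {
  coefs <- if (is.null(c)) c(a = a, b = b) else c(a = a, b = b, c = c)
  if (is.null(predictors))
    predictors <- if (is.null(c)) "h_mean" else c("h50", "fc")
  if (is.null(covariance))
    covariance <- matrix(0, length(coefs), length(coefs),
                         dimnames = list(names(coefs), names(coefs)))
  structure(list(stratum = stratum, predictors = predictors,
                 coefficients = coefs, covariance = covariance,
                 n_plots = NA_integer_, rmse = NA_real_, rmse_pct = NA_real_,
                 bias_pct = NA_real_, adj_r2 = NA_real_),
            class = "biomass_model")
}
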