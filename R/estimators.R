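#' @title Inference engines for mean biomass
#' @description Three estimators of mean aboveground biomass density for a
#'   reporting scope (a stratum, an administrative domain, or their
#'   intersection):
#'
#'   * design-based (DB): the plot sample mean with the simple-random-sampling
#'     variance (the conservative convention for systematic inventory grids);
#'   * model-based (MB): the mean of per-cell model predictions over every
#'     population unit, with a delta-method standard error driven entirely by
#'     the calibration-parameter covariance;
#'   * small-area (SAE): a two-phase regression estimator — a globally fitted
#'     linear working model evaluated at the scope's exhaustive auxiliary
#'     mean, corrected by the scope's mean plot residual.
#'
#'   All half-widths use Student's t at the estimator's stated degrees of
#'   freedom; `rel_se_pct = 100 * epsilon / mean` is the half-width relative
#'   to the mean.
#' @name estimators
NULL

new_estimate <- function(method, mean, se, df, confidence, n = NA, N = NA,
                         scope_type = NA, scope_id = NA, scale_m = NA,
                         flag = NA_character_) {
  eps <- if (is.na(se) || is.na(df) || df < 1) NA_real_
         else stats::qt(1 - (1 - confidence) / 2, df) * se
  structure(list(
    method = method, scope_type = scope_type, scope_id = scope_id,
    scale_m = scale_m, mean = mean, se = se, epsilon = eps,
    rel_se_pct = if (!is.na(eps) && !is.na(mean) && mean > 0)
      100 * eps / mean else NA_real_,
    ci = c(mean - eps, mean + eps), n = n, N = N, df = df,
    confidence = confidence, flag = flag), class = "agbd_estimate")
}

#' @export
print.agbd_estimate <- function(x, ...) {
  cat(sprintf("<%s estimate> mean %.2f Mg/ha, SE %.3f, eps %.3f (rel %.1f%%), n=%s N=%s%s\n",
              x$method, x$mean, x$se, x$epsilon, x$rel_se_pct,
              format(x$n), format(x$N),
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.agbd_estimate <- function(x, ...) {
  data.frame(method = x$method, scope_type = x$scope_type,
             scope_id = as.character(x$scope_id), scale_m = x$scale_m,
             mean = x$mean, se = x$se, epsilon = x$epsilon,
             rel_se_pct = x$rel_se_pct, ci_low = x$ci[1L], ci_high = x$ci[2L],
             n = x$n, N = x$N, flag = x$flag)
}

#' Design-based estimate of mean biomass
#'
#' Sample mean with SRS variance `s^2/n`, SE, half-width
#' `epsilon = t_{n-1, 1-(1-conf)/2} * SE` and relative SE
#' `100 * epsilon / mean`.
#'
#' @param y plot biomass values, Mg/ha.
#' @param confidence CI level (default 0.95).
#' @param allow_insufficient if `TRUE`, n < 2 returns a flagged, un-estimable
#'   result instead of an error (used to propagate sparse scopes as flagged
#'   rows).
#' @return an `agbd_estimate`.
#' @export
estimate_db <- function(y, confidence = 0.95, allow_insufficient = FALSE) {
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < 2L) {
    if (!allow_insufficient)
      stop("insufficient sample: n = ", n, " (need >= 2)")
    return(new_estimate("DB", mean = if (n) mean(y) else NA_real_,
                        se = NA_real_, df = NA, confidence = confidence,
                        n = n, flag = "insufficient sample"))
  }
  se <- sqrt(stats::var(y) / n)
  new_estimate("DB", mean = mean(y), se = se, df = n - 1,
               confidence = confidence, n = n)
}

#' Wall-to-wall biomass prediction map
#'
#' Applies per-stratum power models to a (stamped) metric grid, window by
#' window. Windows whose stratum has no model are a hard error; windows whose
#' height predictor is 0 predict 0.
#'
#' @param metric_grid a [stamp_labels()]-ed [window_metrics()] result.
#' @param models list of [fit_power_model()] objects, named by stratum code.
#' @return biomass prediction [raster_grid()] at the metric-grid resolution.
#' @export
predict_map <- function(metric_grid, models) {
  stopifnot(inherits(metric_grid, "metric_grid"))
  if (is.null(metric_grid$strata))
    stop("metric grid has no stratum labels; run stamp_labels() first")
  df <- metric_grid_df(metric_grid)
  codes <- sort(unique(df$stratum))
  missing <- setdiff(as.character(codes), names(models))
  if (length(missing))
    stop("no biomass model for stratum code(s): ",
         paste(missing, collapse = ", "))
  pred <- numeric(nrow(df))
  for (s in codes) {
    i <- df$stratum == s
    pred[i] <- predict(models[[as.character(s)]], df[i, , drop = FALSE])
  }
  ref <- metric_grid$strata
  raster_grid(matrix(pred, nrow(ref$values), ncol(ref$values)),
              metric_grid$resolution_m, origin = ref$origin)
}

#' Model-based estimate of mean biomass
#'
#' Mean of the model predictions over the scope's N population units. The
#' standard error is the delta-method form
#' `SE = sqrt( (sum_i Z_i)' Cov(beta) (sum_j Z_j) ) / N`, the factorized
#' equivalent of the full double sum over unit pairs (see
#' [mb_se_bruteforce()] for the O(N^2) oracle), with `Z_i` the gradient of
#' the prediction function at unit i. Cells outside the model domain predict
#' 0 with zero gradient. The half-width uses t at N - 1 df (1.96 in the
#' large-N limit).
#'
#' When the scope spans several strata, each stratum's own model is applied
#' and the quadratic forms are summed (models are fitted on disjoint plot
#' sets and treated as independent).
#'
#' @param cells data.frame of the scope's windows: the models' predictor
#'   columns plus, when `models` holds more than one model, a `stratum`
#'   column.
#' @param models a single `biomass_model` or a list named by stratum code.
#' @param confidence CI level.
#' @param scope_type,scope_id,scale_m carried into the result.
#' @return an `agbd_estimate` with `N` = number of population units.
#' @export
estimate_mb <- function(cells, models, confidence = 0.95,
                        scope_type = NA, scope_id = NA, scale_m = NA) {
  if (inherits(models, "biomass_model")) models <- list(models)
  N <- nrow(cells)
  if (N < 1L) stop("model-based estimate needs at least one population unit")
  total_pred <- 0
  var_sum <- 0
  if (length(models) == 1L && is.null(cells$stratum)) {
    groups <- list(seq_len(N))
    mods <- models
  } else {
    if (is.null(cells$stratum))
      stop("multi-model estimate needs a stratum column")
    codes <- sort(unique(cells$stratum))
    missing <- setdiff(as.character(codes), names(models))
    if (length(missing))
      stop("no biomass model for stratum code(s): ",
           paste(missing, collapse = ", "))
    groups <- lapply(codes, function(s) which(cells$stratum == s))
    mods <- models[as.character(codes)]
  }
  for (g in seq_along(groups)) {
    m <- mods[[g]]
    if (is.null(m$covariance)) stop("model has no parameter covariance")
    sub <- cells[groups[[g]], , drop = FALSE]
    total_pred <- total_pred + sum(predict(m, sub))
    sZ <- colSums(model_gradient(m, sub))
    var_sum <- var_sum + drop(t(sZ) %*% m$covariance %*% sZ)
  }
  new_estimate("MB", mean = total_pred / N, se = sqrt(var_sum) / N,
               df = N - 1, confidence = confidence, N = N,
               scope_type = scope_type, scope_id = scope_id,
               scale_m = scale_m)
}

#' Brute-force model-based SE (test oracle)
#'
#' The explicit O(N^2) double sum
#' `sqrt( (1/N^2) * sum_i sum_j Z_i' Cov Z_j )`. Kept as the independent
#' check of the factorized form used by [estimate_mb()]; do not use on large
#' N.
#'
#' @param Z N-by-p gradient matrix.
#' @param covariance p-by-p parameter covariance.
#' @return the SE (scalar).
#' @export
mb_se_bruteforce <- function(Z, covariance) {
  N <- nrow(Z)
  acc <- 0
  for (i in seq_len(N)) for (j in seq_len(N))
    acc <- acc + drop(t(Z[i, ]) %*% covariance %*% Z[j, ])
  sqrt(acc / N^2)
}

#' Fit the small-area working model
#'
#' Ordinary least squares of plot biomass on the auxiliary metrics (default
#' top-of-canopy height h99, mean height and canopy cover) over the FULL
#' second-phase plot set — the model borrows strength globally; the local
#' correction happens per scope in [estimate_sae()]. Coefficient covariance
#' is the homoscedastic `s^2 (X'X)^{-1}`.
#'
#' @param plots plot table with metric columns (see [add_plot_metrics()]).
#' @param predictors auxiliary column names.
#' @param response response column.
#' @return list of class `sae_working_model`: `beta`, `cov_beta`,
#'   `residuals` (per plot, in plot-table order), `predictors`, `n`.
#' @export
fit_sae_working_model <- function(plots, predictors = c("h99", "h_mean", "fc"),
                                  response = "agbd_mg_ha") {
  if (!all(c(predictors, response) %in% names(plots)))
    stop("missing columns: ",
         paste(setdiff(c(predictors, response), names(plots)), collapse = ", "))
  n <- nrow(plots)
  p <- length(predictors) + 1L
  if (n < p + 1L) stop("need at least ", p + 1L, " plots for ", p,
                       " coefficients")
  X <- cbind("(Intercept)" = 1,
             as.matrix(plots[, predictors, drop = FALSE]))
  y <- plots[[response]]
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) stop("rank-deficient working-model design")
  s2 <- sum(fit$residuals^2) / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  structure(list(beta = fit$coefficients, cov_beta = s2 * XtX_inv,
                 residuals = fit$residuals, predictors = predictors, n = n),
            class = "sae_working_model")
}

#' Small-area estimate of mean biomass
#'
#' Two-phase regression estimator with an exhaustive first phase: the working
#' model evaluated at the scope's exhaustive auxiliary mean, plus the mean
#' residual of the scope's own plots,
#' `mean = xbar_G' beta + mean(residuals_G)`. The variance is the sum of a
#' coefficient term `xbar_G' Cov(beta) xbar_G`, an auxiliary-mean term
#' `beta' Cov(xbar_G) beta` (zero when the first phase is a census of the
#' scope, the default), and a residual term `var(residuals_G) / n_G`. The
#' half-width uses t at `n_G - 1` df.
#'
#' With no local plot the synthetic-regression mean `xbar_G' beta` is
#' returned flagged, with no variance; with one plot the corrected mean is
#' returned, variance flagged.
#'
#' @param xbar_G exhaustive mean of the auxiliary vector (leading 1 for the
#'   intercept) over the scope's population units.
#' @param working_model a [fit_sae_working_model()] result.
#' @param residuals_G working-model residuals of the plots inside the scope.
#' @param confidence CI level.
#' @param cov_xbar optional covariance of the auxiliary mean (non-exhaustive
#'   first phase); default zero.
#' @param scope_type,scope_id carried into the result.
#' @return an `agbd_estimate` with `n` = number of local plots.
#' @export
estimate_sae <- function(xbar_G, working_model, residuals_G,
                         confidence = 0.95, cov_xbar = NULL,
                         scope_type = NA, scope_id = NA) {
  stopifnot(inherits(working_model, "sae_working_model"))
  beta <- working_model$beta
  if (length(xbar_G) != length(beta))
    stop("auxiliary mean length ", length(xbar_G),
         " != coefficient length ", length(beta))
  n_G <- length(residuals_G)
  synth <- drop(crossprod(xbar_G, beta))
  if (n_G == 0L)
    return(new_estimate("SAE", mean = synth, se = NA_real_, df = NA,
                        confidence = confidence, n = 0L,
                        scope_type = scope_type, scope_id = scope_id,
                        flag = "no local plots; synthetic mean, variance unavailable"))
  est <- synth + mean(residuals_G)
  if (n_G == 1L)
    return(new_estimate("SAE", mean = est, se = NA_real_, df = NA,
                        confidence = confidence, n = 1L,
                        scope_type = scope_type, scope_id = scope_id,
                        flag = "single local plot; variance unavailable"))
  v <- drop(t(xbar_G) %*% working_model$cov_beta %*% xbar_G) +
    stats::var(residuals_G) / n_G
  if (!is.null(cov_xbar))
    v <- v + drop(t(beta) %*% cov_xbar %*% beta)
  new_estimate("SAE", mean = est, se = sqrt(v), df = n_G - 1,
               confidence = confidence, n = n_G,
               scope_type = scope_type, scope_id = scope_id)
}

#' Empirical confidence-interval coverage
#'
#' Replicates the sampling stage of the pipeline over one fixed landscape —
#' each replicate draws a fresh systematic-grid offset and fresh plot
#' measurement noise — computes the chosen estimator's CI at landscape scope,
#' and reports the proportion of replicates whose CI contains the true
#' landscape mean (with a binomial SE). This is design-based replication
#' against a fixed truth. The DB replicate uses all retained plots; the SAE
#' replicate refits the working model per replicate and uses the exhaustive
#' auxiliary mean of the baseline-resolution metric grid.
#'
#' @param landscape a [generate_landscape()] result.
#' @param method "DB" or "SAE".
#' @param n_replicates number of replicate samplings (>= 50).
#' @param spacing_m,radius_m,noise_sdlog sampling design; defaults from the
#'   landscape's config (cover filter off: coverage probes the estimator,
#'   not the retention rule).
#' @param baseline_m SAE auxiliary resolution (default 44).
#' @param confidence CI level.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return list: coverage, binomial se, n_replicates, true_mean.
#' @export
empirical_coverage <- function(landscape, method = c("DB", "SAE"),
                               n_replicates = 200, spacing_m = NULL,
                               radius_m = NULL, noise_sdlog = NULL,
                               baseline_m = 44, confidence = 0.95,
                               seed = 1L) {
  method <- match.arg(method)
  if (n_replicates < 50L) stop("need >= 50 replicates")
  cfg <- landscape$config
  if (is.null(spacing_m)) spacing_m <- cfg$plot_spacing_m
  if (is.null(radius_m)) radius_m <- cfg$plot_radius_m
  if (is.null(noise_sdlog)) noise_sdlog <- cfg$noise_sdlog
  truth_mean <- landscape$truth$table$true_mean[
    landscape$truth$table$scope_type == "landscape"]

  if (method == "SAE") {
    mg <- window_metrics(landscape$chm, baseline_m,
                         metrics = c("h99", "h_mean", "fc"))
    aux <- metric_grid_df(mg)
    xbar <- c(1, colMeans(aux[, c("h99", "h_mean", "fc")]))
  }

  hits <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    plots <- sample_nfi_plots(landscape$chm, landscape$strata,
                              landscape$domains, landscape$truth,
                              spacing_m = spacing_m, radius_m = radius_m,
                              cover_min = 0, noise_sdlog = noise_sdlog,
                              seed = seed + r)
    if (method == "DB") {
      est <- estimate_db(plots$agbd_mg_ha, confidence)
    } else {
      plots <- add_plot_metrics(plots, landscape$chm, radius_m)
      wm <- fit_sae_working_model(plots)
      est <- estimate_sae(xbar, wm, wm$residuals, confidence)
    }
    hits[r] <- est$ci[1L] <= truth_mean && truth_mean <= est$ci[2L]
  }
  cov <- mean(hits)
  list(coverage = cov, se = sqrt(cov * (1 - cov) / n_replicates),
       n_replicates = n_replicates, true_mean = truth_mean)
}
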