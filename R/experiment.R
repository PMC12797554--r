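#' Experiment specification
#'
#' The estimator-by-scale comparison: DB and SAE once per scope, MB once per
#' scope and prediction resolution, with the plot-native baseline resolution
#' (44 m, the square-cell equivalent of a 25-m-radius plot) anchoring the
#' relative-change column. Calibration models are fitted once at the baseline
#' scale and transferred unchanged to every other resolution — the scale
#' transfer, not refitting, is the experiment.
#'
#' @param resolutions prediction scales, m.
#' @param baseline_m baseline scale (must be one of `resolutions`).
#' @param scopes which reporting scopes to tabulate.
#' @param confidence CI level.
#' @param n_replicates replicates for coverage runs.
#' @param seed RNG seed for coverage runs.
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(resolutions = c(10, 25, 44, 100),
                            baseline_m = 44,
                            scopes = c("stratum", "domain"),
                            confidence = 0.95, n_replicates = 200,
                            seed = 1L) {
  if (!baseline_m %in% resolutions)
    stop("baseline_m must be one of the resolutions")
  scopes <- match.arg(scopes, c("stratum", "domain", "stratum_x_domain"),
                      several.ok = TRUE)
  structure(list(resolutions = resolutions, baseline_m = baseline_m,
                 scopes = scopes, confidence = confidence,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Relative change against the baseline estimate
#'
#' `100 * (x - baseline) / baseline` (percent).
#'
#' @param x,baseline estimate means (or any positives).
#' @return percent change.
#' @export
relative_change <- function(x, baseline) {
  if (any(baseline == 0)) stop("baseline mean is zero")
  100 * (x - baseline) / baseline
}

#' Upscale a mean estimate to a total stock
#'
#' Two reporting conventions: `mean_x_area` (DB, SAE) multiplies the mean
#' (Mg/ha) by the scope area (ha); `pixel_sum` (MB) sums the biomass weight
#' of every prediction cell, `sum(pred * cell_area_ha)`, which lets the
#' wall-to-wall map down-weight gaps and low-stature cells inside the scope
#' boundary.
#'
#' @param mean_mg_ha scope mean, Mg/ha (`mean_x_area` mode).
#' @param scope_area_ha scope area, ha (`mean_x_area` mode).
#' @param mode "mean_x_area" or "pixel_sum".
#' @param prediction biomass [raster_grid()] (`pixel_sum` mode).
#' @param cells optional indices/logical mask restricting `pixel_sum` to the
#'   scope's cells (default: all non-NA cells).
#' @return total biomass, Mg.
#' @export
upscale_totals <- function(mean_mg_ha = NULL, scope_area_ha = NULL,
                           mode = c("mean_x_area", "pixel_sum"),
                           prediction = NULL, cells = NULL) {
  mode <- match.arg(mode)
  if (mode == "mean_x_area") {
    if (is.null(mean_mg_ha) || is.null(scope_area_ha))
      stop("mean_x_area mode needs mean_mg_ha and scope_area_ha")
    if (scope_area_ha <= 0) stop("scope area must be positive")
    return(mean_mg_ha * scope_area_ha)
  }
  if (is.null(prediction) || !inherits(prediction, "raster_grid"))
    stop("pixel_sum mode needs a prediction raster")
  v <- prediction$values
  if (!is.null(cells)) v <- v[cells]
  v <- v[!is.na(v)]
  sum(v) * prediction$cell_size^2 / 1e4
}

# scope iterator: list of (scope_type, scope_id, stratum, domain)
scope_list <- function(scopes, strata_codes, domain_codes) {
  out <- list()
  if ("stratum" %in% scopes)
    for (s in strata_codes)
      out[[length(out) + 1L]] <- list(type = "stratum", id = as.character(s),
                                      stratum = s, domain = NA)
  if ("domain" %in% scopes)
    for (d in domain_codes)
      out[[length(out) + 1L]] <- list(type = "domain", id = as.character(d),
                                      stratum = NA, domain = d)
  if ("stratum_x_domain" %in% scopes)
    for (s in strata_codes) for (d in domain_codes)
      out[[length(out) + 1L]] <- list(type = "stratum_x_domain",
                                      id = paste0(s, ":", d),
                                      stratum = s, domain = d)
  out
}

scope_rows <- function(df, sc) {
  keep <- rep(TRUE, nrow(df))
  if (!is.na(sc$stratum)) keep <- keep & df$stratum == sc$stratum
  if (!is.na(sc$domain)) keep <- keep & df$domain == sc$domain
  which(keep)
}

#' Run the estimator-by-scale comparison
#'
#' For every scope: the DB estimate from the scope's plots; the SAE estimate
#' from the globally fitted working model, the scope's exhaustive
#' baseline-resolution auxiliary means and the scope's plot residuals; and
#' one MB estimate per prediction resolution, always using the
#' baseline-calibrated per-stratum models. Totals use `mean_x_area` for
#' DB/SAE and `pixel_sum` for MB; every row carries the relative change of
#' its mean against the scope's baseline MB mean. Scopes with too few plots
#' yield flagged rows, never silent drops.
#'
#' @param spec an [experiment_spec()].
#' @param landscape a [generate_landscape()] result.
#' @param plots plot table WITH metric columns ([add_plot_metrics()]).
#' @param models per-stratum [fit_power_model()] list, named by stratum code,
#'   calibrated at the baseline scale.
#' @return list: `comparison` (data.frame, one row per scope x method x
#'   scale), `metric_grids` (per resolution, stamped), `working_model`.
#' @export
run_full_experiment <- function(spec, landscape, plots, models) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (!all(c("h99", "h_mean", "fc") %in% names(plots)))
    stop("plots lack metric columns; run add_plot_metrics() first")
  truth_tab <- landscape$truth$table
  strata_codes <- sort(unique(as.vector(landscape$strata$values)))
  domain_codes <- sort(unique(as.vector(landscape$domains$values)))
  scopes <- scope_list(spec$scopes, strata_codes, domain_codes)

  # per-resolution stamped metric grids and window tables
  mgs <- lapply(spec$resolutions, function(res)
    stamp_labels(window_metrics(landscape$chm, res),
                 landscape$strata, landscape$domains))
  names(mgs) <- as.character(spec$resolutions)
  mdfs <- lapply(mgs, metric_grid_df)
  pred_maps <- lapply(mgs, predict_map, models = models)

  wm <- fit_sae_working_model(plots)
  aux_cols <- c("h99", "h_mean", "fc")
  base_df <- mdfs[[as.character(spec$baseline_m)]]

  scope_area <- function(sc) {
    tt <- truth_tab[truth_tab$scope_type == sc$type &
                      (is.na(sc$stratum) | truth_tab$stratum == sc$stratum) &
                      (is.na(sc$domain) | truth_tab$domain == sc$domain), ]
    if (nrow(tt) == 1L) tt$area_ha else NA_real_
  }

  rows <- list()
  push <- function(est, area_ha, total, rel = NA_real_) {
    df <- as.data.frame(est)
    df$area_ha <- area_ha
    df$total_mg <- total
    df$rel_change_pct <- rel
    rows[[length(rows) + 1L]] <<- df
  }

  for (sc in scopes) {
    area_ha <- scope_area(sc)
    pi <- scope_rows(plots, sc)

    # baseline MB mean anchors the relative-change column for this scope
    base_cells <- base_df[scope_rows(base_df, sc), , drop = FALSE]
    base_mb <- if (nrow(base_cells))
      estimate_mb(base_cells, models, spec$confidence, sc$type, sc$id,
                  spec$baseline_m) else NULL

    db <- estimate_db(plots$agbd_mg_ha[pi], spec$confidence,
                      allow_insufficient = TRUE)
    db$scope_type <- sc$type; db$scope_id <- sc$id
    push(db, area_ha,
         if (!is.na(db$mean) && !is.na(area_ha))
           upscale_totals(db$mean, area_ha) else NA_real_,
         if (!is.null(base_mb) && !is.na(db$mean))
           relative_change(db$mean, base_mb$mean) else NA_real_)

    if (nrow(base_cells)) {
      xbar <- c(1, colMeans(base_cells[, aux_cols]))
      sae <- estimate_sae(xbar, wm, wm$residuals[pi], spec$confidence,
                          scope_type = sc$type, scope_id = sc$id)
      push(sae, area_ha,
           if (!is.na(sae$mean) && !is.na(area_ha))
             upscale_totals(sae$mean, area_ha) else NA_real_,
           if (!is.null(base_mb)) relative_change(sae$mean, base_mb$mean)
           else NA_real_)
    }

    for (res in spec$resolutions) {
      mdf <- mdfs[[as.character(res)]]
      ci <- scope_rows(mdf, sc)
      if (!length(ci)) next
      mb <- if (res == spec$baseline_m && !is.null(base_mb)) base_mb
            else estimate_mb(mdf[ci, , drop = FALSE], models,
                             spec$confidence, sc$type, sc$id, res)
      pm <- pred_maps[[as.character(res)]]
      keep <- rep(TRUE, length(pm$values))
      if (!is.na(sc$stratum))
        keep <- keep & as.vector(mgs[[as.character(res)]]$strata$values) == sc$stratum
      if (!is.na(sc$domain))
        keep <- keep & as.vector(mgs[[as.character(res)]]$domains$values) == sc$domain
      total <- upscale_totals(mode = "pixel_sum", prediction = pm,
                              cells = keep)
      push(mb, area_ha, total,
           if (!is.null(base_mb)) relative_change(mb$mean, base_mb$mean)
           else NA_real_)
    }
  }
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  list(comparison = comparison, metric_grids = mgs, working_model = wm,
       prediction_maps = pred_maps)
}
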