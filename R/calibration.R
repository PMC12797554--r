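#' Fit statistics for a biomass calibration model
#'
#' `RMSE = sqrt(sum((y - yhat)^2) / n)`, `RMSE% = 100 * RMSE / mean(y)`,
#' `bias% = 100 * sum(yhat - y) / (n * mean(y))` (positive = overprediction;
#' the sign convention is fixed here and documented, it is not universal),
#' and an adjusted pseudo-R-squared
#' `1 - (1 - R2) * (n - 1) / (n - k - 1)` with `R2 = 1 - SSE/SST`.
#'
#' @param observed,predicted equal-length numeric vectors, Mg/ha.
#' @param k_params number of fitted parameters.
#' @return named list: rmse, rmse_pct, bias_pct, adj_r2.
#' @export
fit_statistics <- function(observed, predicted, k_params) {
  n <- length(observed)
  if (length(predicted) != n) stop("observed/predicted length mismatch")
  if (n <= k_params) stop("need n > k_params")
  ybar <- mean(observed)
  if (ybar == 0) stop("mean of observed values is zero")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - ybar)^2)
  rmse <- sqrt(sse / n)
  r2 <- if (sst > 0) 1 - sse / sst else as.numeric(sse == 0)
  list(rmse = rmse,
       rmse_pct = 100 * rmse / ybar,
       bias_pct = 100 * sum(predicted - observed) / (n * ybar),
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k_params - 1))
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is from regressing column k on the
#' remaining columns (with intercept). Perfectly collinear columns report
#' `Inf`.
#'
#' @param x numeric matrix, >= 2 columns and >= 3 rows.
#' @return numeric vector of VIFs, one per column.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L || nrow(x) < 3L) stop("vif needs >= 2 columns, >= 3 rows")
  if (any(apply(x, 2L, stats::sd) == 0))
    stop("constant column in VIF design")
  vapply(seq_len(ncol(x)), function(k) {
    fit <- stats::lm.fit(cbind(1, x[, -k, drop = FALSE]), x[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, k] - mean(x[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Fit a per-stratum power-law biomass model
#'
#' Nonlinear least squares for `AGBD = a * h1^b` (one predictor) or
#' `AGBD = a * h1^b * h2^c` (two predictors), the standard area-based
#' calibration form with a height percentile as `h1` and canopy cover as
#' `h2`. Starting values come from OLS on the log-log linearisation; the
#' parameter covariance is the Gauss-Newton estimate `s^2 (J'J)^{-1}` at the
#' solution. Plots where any predictor or the response is not strictly
#' positive are excluded from the fit (the power model and its log start are
#' undefined there); prediction at such cells is defined as 0 by
#' [predict.biomass_model()].
#'
#' @param plots data.frame with the response and predictor columns.
#' @param predictors character: one height metric, optionally followed by a
#'   cover metric, naming columns of `plots`.
#' @param response response column name (Mg/ha).
#' @param stratum stratum code carried in the result.
#' @param min_plots minimum usable plots (default 10).
#' @return object of class `biomass_model`: coefficients (a, b and, for
#'   two-predictor fits, c), covariance matrix, n_plots and the fit
#'   statistics of [fit_statistics()].
#' @export
fit_power_model <- function(plots, predictors, response = "agbd_mg_ha",
                            stratum = NA, min_plots = 10L) {
  if (!all(c(predictors, response) %in% names(plots)))
    stop("missing columns: ",
         paste(setdiff(c(predictors, response), names(plots)), collapse = ", "))
  two <- length(predictors) == 2L
  y <- plots[[response]]
  h1 <- plots[[predictors[1L]]]
  h2 <- if (two) plots[[predictors[2L]]] else rep(1, length(y))
  ok <- y > 0 & h1 > 0 & h2 > 0
  d <- data.frame(y = y[ok], h1 = h1[ok], h2 = h2[ok])
  if (nrow(d) < min_plots)
    stop("stratum ", stratum, ": only ", nrow(d),
         " usable plots (need >= ", min_plots, ")")

  X <- cbind(1, log(d$h1))
  if (two) X <- cbind(X, log(d$h2))
  cf <- stats::lm.fit(X, log(d$y))$coefficients
  start <- if (two) list(a = exp(cf[[1L]]), b = cf[[2L]], c = cf[[3L]])
           else list(a = exp(cf[[1L]]), b = cf[[2L]])
  form <- if (two) y ~ a * h1^b * h2^c else y ~ a * h1^b
  fit <- tryCatch(
    stats::nls(form, data = d, start = start,
               control = stats::nls.control(maxiter = 200,
                                            scaleOffset = 1)),
    error = function(e)
      stop("stratum ", stratum, ": nonlinear fit failed (", conditionMessage(e),
           "); start values a=", signif(start$a, 4), " b=", signif(start$b, 4),
           if (two) paste0(" c=", signif(start$c, 4)), call. = FALSE))
  est <- stats::coef(fit)
  pred <- stats::fitted(fit)
  stats_ <- fit_statistics(d$y, pred, length(est))
  structure(list(
    stratum = stratum, predictors = predictors,
    coefficients = est, covariance = stats::vcov(fit),
    n_plots = nrow(d), rmse = stats_$rmse, rmse_pct = stats_$rmse_pct,
    bias_pct = stats_$bias_pct, adj_r2 = stats_$adj_r2),
    class = "biomass_model")
}

#' @export
print.biomass_model <- function(x, ...) {
  cat(sprintf("<biomass_model> stratum %s: AGBD = %.4g * %s^%.4g%s\n",
              format(x$stratum), x$coefficients[["a"]], x$predictors[1L],
              x$coefficients[["b"]],
              if (length(x$predictors) == 2L)
                sprintf(" * %s^%.4g", x$predictors[2L], x$coefficients[["c"]])
              else ""))
  cat(sprintf("  n = %d, RMSE = %.2f Mg/ha (%.1f%%), bias = %.2f%%, adj.R2 = %.3f\n",
              x$n_plots, x$rmse, x$rmse_pct, x$bias_pct, x$adj_r2))
  invisible(x)
}

#' Predict biomass density from a fitted power model
#'
#' Rows where any required predictor is `<= 0` predict 0 Mg/ha (outside the
#' model's positive domain; in practice treeless windows).
#'
#' @param object a [fit_power_model()] result.
#' @param newdata data.frame containing the model's predictor columns.
#' @param ... unused.
#' @return numeric vector of predictions, Mg/ha.
#' @export
predict.biomass_model <- function(object, newdata, ...) {
  cf <- object$coefficients
  h1 <- newdata[[object$predictors[1L]]]
  out <- numeric(length(h1))
  if (length(object$predictors) == 2L) {
    h2 <- newdata[[object$predictors[2L]]]
    ok <- h1 > 0 & h2 > 0
    out[ok] <- cf[["a"]] * h1[ok]^cf[["b"]] * h2[ok]^cf[["c"]]
  } else {
    ok <- h1 > 0
    out[ok] <- cf[["a"]] * h1[ok]^cf[["b"]]
  }
  out
}

# Gradient of the power model w.r.t. (a, b[, c]) row-wise; zero rows where
# the prediction is zero (out-of-domain cells contribute nothing to the
# model-based variance).
model_gradient <- function(object, newdata) {
  cf <- object$coefficients
  f <- predict(object, newdata)
  h1 <- newdata[[object$predictors[1L]]]
  p <- length(cf)
  Z <- matrix(0, length(f), p,
              dimnames = list(NULL, names(cf)))
  ok <- f > 0
  Z[ok, 1L] <- f[ok] / cf[["a"]]
  Z[ok, 2L] <- f[ok] * log(h1[ok])
  if (p == 3L) {
    h2 <- newdata[[object$predictors[2L]]]
    Z[ok, 3L] <- f[ok] * log(h2[ok])
  }
  Z
}

#' Exhaustive two-predictor selection with a collinearity screen
#'
#' Searches every (height percentile, cover) candidate pair on the log-log
#' scale, discards pairs whose VIF exceeds `vif_max` (default 10), fits the
#' nonlinear power model for the surviving pairs and returns the pair with
#' the lowest RMSE. If every pair fails the screen (or no cover candidate is
#' given), the best single height predictor is returned instead.
#'
#' @param plots data.frame of one stratum's plots.
#' @param candidate_heights,candidate_covers column names to search.
#' @param response response column.
#' @param stratum stratum code for messages.
#' @param vif_max collinearity threshold.
#' @return list: `predictors` (character, length 1 or 2), `model` (the winning
#'   [fit_power_model()]), `searched` (data.frame of candidates with VIF and
#'   RMSE).
#' @export
select_predictors <- function(plots, candidate_heights,
                              candidate_covers = character(),
                              response = "agbd_mg_ha", stratum = NA,
                              vif_max = 10) {
  if (length(candidate_heights) < 1L)
    stop("need at least one height candidate")
  y <- plots[[response]]
  try_fit <- function(preds) {
    tryCatch(fit_power_model(plots, preds, response, stratum),
             error = function(e) NULL)
  }
  recs <- list()
  best <- NULL
  for (h in candidate_heights) for (cv in candidate_covers) {
    ok <- y > 0 & plots[[h]] > 0 & plots[[cv]] > 0
    if (sum(ok) < 3L) next
    v <- tryCatch(max(vif(cbind(log(plots[[h]][ok]), log(plots[[cv]][ok])))),
                  error = function(e) Inf)
    rec <- data.frame(h1 = h, h2 = cv, vif = v, rmse = NA_real_)
    if (v <= vif_max) {
      m <- try_fit(c(h, cv))
      if (!is.null(m)) {
        rec$rmse <- m$rmse
        if (is.null(best) || m$rmse < best$rmse) best <- m
      }
    }
    recs[[length(recs) + 1L]] <- rec
  }
  if (is.null(best)) {     # fall back to the best single height predictor
    for (h in candidate_heights) {
      m <- try_fit(h)
      if (!is.null(m)) {
        recs[[length(recs) + 1L]] <- data.frame(h1 = h, h2 = NA, vif = NA,
                                                rmse = m$rmse)
        if (is.null(best) || m$rmse < best$rmse) best <- m
      }
    }
  }
  if (is.null(best))
    stop("stratum ", stratum, ": no fittable predictor candidate")
  list(predictors = best$predictors, model = best,
       searched = do.call(rbind, recs))
}

#' Serialize / deserialize biomass models
#'
#' Models travel as JSON: stratum, predictors, params, covariance (row-major),
#' n, rmse, rmse_pct, bias_pct, adj_r2.
#'
#' @param models named list of `biomass_model` objects.
#' @param path output / input file.
#' @return `read_models` returns the named list of models.
#' @export
write_models <- function(models, path) {
  ser <- lapply(models, function(m) list(
    stratum = m$stratum, predictors = m$predictors,
    params = as.list(m$coefficients),
    cov = as.vector(t(m$covariance)), n = m$n_plots,
    rmse = m$rmse, rmse_pct = m$rmse_pct, bias_pct = m$bias_pct,
    adj_r2 = m$adj_r2))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  out <- lapply(raw, function(m) {
    p <- length(m$params)
    structure(list(
      stratum = m$stratum, predictors = unlist(m$predictors),
      coefficients = unlist(m$params),
      covariance = matrix(unlist(m$cov), p, p, byrow = TRUE,
                          dimnames = list(names(m$params), names(m$params))),
      n_plots = m$n, rmse = m$rmse, rmse_pct = m$rmse_pct,
      bias_pct = m$bias_pct, adj_r2 = m$adj_r2), class = "biomass_model")
  })
  names(out) <- names(raw)
  out
}
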