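test_that("design-based closed forms", {
  # constant sample: zero dispersion
  e <- estimate_db(c(50, 50, 50))
  expect_equal(e$mean, 50)
  expect_equal(e$se, 0)
  expect_equal(e$rel_se_pct, 0)

  # {10,20,30}: s2 = 100, SE = sqrt(100/3), eps = t_{2,.975} * SE
  e <- estimate_db(c(10, 20, 30))
  expect_equal(e$mean, 20)
  expect_equal(e$se, sqrt(100 / 3))
  expect_equal(e$epsilon, stats::qt(0.975, 2) * sqrt(100 / 3))
  expect_equal(e$rel_se_pct, 100 * e$epsilon / 20)
  expect_equal(unname(e$ci), c(20 - e$epsilon, 20 + e$epsilon))

  # large-n limit: t -> 1.96
  set.seed(1)
  big <- estimate_db(stats::rnorm(1e5, 100, 10))
  expect_equal(big$epsilon / big$se, stats::qnorm(0.975), tolerance = 1e-3)

  expect_error(estimate_db(5), "insufficient")
  flagged <- estimate_db(numeric(), allow_insufficient = TRUE)
  expect_true(is.na(flagged$mean))
  expect_match(flagged$flag, "insufficient")
})

test_that("model-based SE: factorized form equals the hand expansion", {
  # two cells, f = a*h with h = {2,4} and var(a) = v -> SE = 3*sqrt(v)
  v <- 0.04
  m <- fixed_model(1, 1, covariance = matrix(c(v, 0, 0, 0), 2, 2,
                                             dimnames = list(c("a", "b"),
                                                             c("a", "b"))))
  cells <- data.frame(h_mean = c(2, 4))
  e <- estimate_mb(cells, m)
  expect_equal(e$mean, 3)
  expect_equal(e$se, 3 * sqrt(v))

  # zero parameter covariance: SE = 0 regardless of cells
  z <- fixed_model(2, 1.3)
  set.seed(2)
  e0 <- estimate_mb(data.frame(h_mean = rexp(30, 1 / 9)), z)
  expect_equal(e0$se, 0)

  # N identical cells: mean equals the single-cell prediction
  mm <- fixed_model(0.5, 1.5,
                    covariance = matrix(c(0.01, 0.002, 0.002, 0.004), 2, 2))
  same <- data.frame(h_mean = rep(6, 25))
  es <- estimate_mb(same, mm)
  expect_equal(es$mean, 0.5 * 6^1.5)
  e1 <- estimate_mb(data.frame(h_mean = 6), mm)
  expect_equal(es$se, e1$se)   # per-unit gradient identical, N cancels
})

test_that("factorized SE equals the O(N^2) double-sum oracle", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(5:50, 1)
    cells <- data.frame(h50 = rexp(n, 1 / 10) + 2, fc = runif(n, 0.05, 1))
    A <- matrix(rnorm(9, sd = 0.05), 3, 3)
    covm <- crossprod(A)
    dimnames(covm) <- list(c("a", "b", "c"), c("a", "b", "c"))
    m <- fixed_model(0.01, 1.1, 1.5, covariance = covm,
                     predictors = c("h50", "fc"))
    cells$h50[1] <- 0                      # a zero-gradient cell in the mix
    e <- estimate_mb(cells, m)
    Z <- forestscale:::model_gradient(m, cells)
    expect_equal(e$se, mb_se_bruteforce(Z, covm) / 1, tolerance = 1e-10)
  }
})

test_that("prediction maps honour stratum models and the zero rule", {
  chm <- rg(c(rep(8, 8), rep(0, 8)), 4, 4)   # east half treeless
  strata <- rg(rep(c(1, 1, 2, 2), each = 4), 4, 4)
  domains <- rg(rep(1, 16), 4, 4)
  mg <- stamp_labels(window_metrics(chm, 2), strata, domains)
  models <- list("1" = fixed_model(1, 1, predictors = "h_mean"),
                 "2" = fixed_model(3, 1, predictors = "h_mean"))
  pm <- predict_map(mg, models)   # 2x2 windows: west pair 8, east pair 0
  expect_equal(as.vector(pm$values), c(8, 8, 0, 0))
  expect_error(predict_map(mg, models["1"]), "no biomass model")
  expect_error(predict_map(window_metrics(chm, 2), models), "stamp_labels")
})

test_that("SAE: working model, estimator algebra and reductions", {
  set.seed(21)
  n <- 40
  plots <- data.frame(h99 = rexp(n, 1 / 15) + 2, h_mean = rexp(n, 1 / 8),
                      fc = runif(n))
  beta_true <- c(5, 2, 1.5, 30)
  plots$agbd_mg_ha <- beta_true[1] + beta_true[2] * plots$h99 +
    beta_true[3] * plots$h_mean + beta_true[4] * plots$fc
  wm <- fit_sae_working_model(plots)
  # exactly linear response: zero residuals, exact coefficients
  expect_equal(unname(wm$beta), beta_true, tolerance = 1e-8)
  expect_equal(max(abs(wm$residuals)), 0, tolerance = 1e-8)
  # permutation invariance
  perm <- sample(n)
  wm2 <- fit_sae_working_model(plots[perm, ])
  expect_equal(wm2$beta, wm$beta, tolerance = 1e-10)

  # coefficient covariance is s^2 (X'X)^{-1}: check on an orthogonal design
  # scaled so X'X = n I, where it must equal (s^2 / n) I exactly
  no <- 32
  Xo <- cbind(rep(c(1, -1), no / 2), rep(c(1, 1, -1, -1), no / 4))
  o <- data.frame(h99 = Xo[, 1], h_mean = Xo[, 2])
  set.seed(5)
  o$agbd_mg_ha <- Xo %*% c(2, 3) + rnorm(no)
  wmo <- fit_sae_working_model(o, predictors = c("h99", "h_mean"))
  s2 <- sum(wmo$residuals^2) / (no - 3)
  expect_equal(unname(diag(wmo$cov_beta)), rep(s2 / no, 3), tolerance = 1e-10)

  expect_error(fit_sae_working_model(plots[1:4, ]), "at least")
  bad <- plots; bad$h_mean <- bad$h99
  expect_error(fit_sae_working_model(bad), "rank-deficient")
})

test_that("SAE with an intercept-only model reduces to the local DB mean", {
  set.seed(13)
  y <- rexp(30, 1 / 80)
  g <- rep(c(1, 2, 3), each = 10)
  tab <- data.frame(agbd_mg_ha = y)
  wm <- fit_sae_working_model(tab, predictors = character())
  for (d in 1:3) {
    res_g <- wm$residuals[g == d]
    sae <- estimate_sae(1, wm, res_g)
    expect_equal(sae$mean, mean(y[g == d]))
    expect_equal(sae$se^2, wm$cov_beta[1, 1] + stats::var(res_g) / 10)
  }
  # zero residuals in G: mean is the synthetic prediction, third term 0
  sae0 <- estimate_sae(1, wm, rep(0, 5))
  expect_equal(sae0$mean, unname(wm$beta[1]))
  expect_equal(sae0$se^2, unname(wm$cov_beta[1, 1]))
})

test_that("SAE flags sparse scopes and is monotone in local n", {
  set.seed(3)
  plots <- data.frame(h99 = rexp(50, 1 / 15), h_mean = rexp(50, 1 / 8),
                      fc = runif(50))
  plots$agbd_mg_ha <- 10 + 2 * plots$h99 + rnorm(50, 0, 12)
  wm <- fit_sae_working_model(plots)
  xbar <- c(1, 14, 8, 0.6)
  none <- estimate_sae(xbar, wm, numeric())
  expect_match(none$flag, "no local plots")
  expect_equal(none$mean, sum(xbar * wm$beta))
  one <- estimate_sae(xbar, wm, 2.5)
  expect_match(one$flag, "single local plot")
  expect_true(is.na(one$se))

  # same residual spread, n = 5 vs n = 40: relative SE strictly larger at 5
  spread <- scale(rnorm(40))[, 1] * 15
  sae5 <- estimate_sae(xbar, wm, spread[1:5] - mean(spread[1:5]))
  sae40 <- estimate_sae(xbar, wm, spread - mean(spread))
  expect_gt(sae5$rel_se_pct, sae40$rel_se_pct)
  expect_error(estimate_sae(c(1, 2), wm, 1:5), "length")
})

test_that("DB relative SE shrinks on nested subsamples", {
  set.seed(17)
  y <- rexp(256, 1 / 70)
  rel <- vapply(c(16, 64, 256), function(n)
    estimate_db(y[1:n])$rel_se_pct, numeric(1))
  expect_true(all(diff(rel) < 0))
})
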