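test_that("four-point toy matches the explicit sandwich arithmetic", {
  x <- c(0, 1, 2, 3); y <- c(1, 2, 2, 4)
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- fit_ols_robust(y, X, hc_type = "HC1")
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  e <- y - drop(X %*% beta)
  meat <- t(X) %*% diag(4 / 2 * e^2) %*% X
  V <- XtX_inv %*% meat %*% XtX_inv
  expect_equal(unname(f$coefficients), unname(drop(beta)),
               tolerance = 1e-12)
  expect_equal(unname(f$se), unname(sqrt(diag(V))), tolerance = 1e-12)
  expect_equal(f$df_residual, 2L)
  # t and p from the same arithmetic
  expect_equal(unname(f$p_value),
               unname(2 * pt(-abs(drop(beta) / sqrt(diag(V))), 2)),
               tolerance = 1e-12)
})

test_that("exact linear data give a perfect fit with zero robust SEs", {
  x <- 1:8; y <- 2 + 3 * x
  f <- fit_ols_robust(y, cbind(1, x))
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(unname(f$se), c(0, 0), tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("centered regressor makes the intercept the outcome mean", {
  set.seed(12)
  x <- scale(rnorm(40), scale = FALSE)
  y <- 5 + 2 * x + rnorm(40)
  f <- fit_ols_robust(y, cbind(`(Intercept)` = 1, x = drop(x)))
  expect_equal(unname(f$coefficients[1]), mean(y), tolerance = 1e-10)
})

test_that("HC flavours are ordered and scale equivariance holds", {
  set.seed(5)
  x <- rnorm(30); y <- 1 + x + rnorm(30) * (1 + 0.5 * abs(x))
  X <- cbind(`(Intercept)` = 1, x = x)
  se <- sapply(c("HC0", "HC1", "HC2", "HC3"), function(h)
    fit_ols_robust(y, X, hc_type = h)$se)
  expect_true(all(se[, "HC0"] <= se[, "HC1"]))
  expect_true(all(se[, "HC0"] <= se[, "HC2"]))
  expect_true(all(se[, "HC2"] <= se[, "HC3"]))
  f1 <- fit_ols_robust(y, X)
  f2 <- fit_ols_robust(y, cbind(`(Intercept)` = 1, x = 10 * x))
  expect_equal(f2$coefficients[["x"]], f1$coefficients[["x"]] / 10,
               tolerance = 1e-10)
  expect_equal(f2$t[["x"]], f1$t[["x"]], tolerance = 1e-10)
})

test_that("residuals are orthogonal to the design in every fit", {
  b <- generate_cbo_panel(generator_config(seed = 17))
  adj <- adjust_scores(compute_scores(b$practice_matrix), b$context_table)
  fits <- fit_performance_models(adj, b$performance_panel)
  for (f in fits) {
    expect_equal(sum(f$residuals), 0, tolerance = 1e-6)
    expect_lt(abs(cor(f$residuals, f$fitted)), 1e-6)
  }
})

test_that("agreement with stats::lm as an independent estimator", {
  set.seed(77)
  x1 <- rnorm(25); x2 <- rnorm(25); y <- 1 + x1 - 2 * x2 + rnorm(25)
  f <- fit_ols_robust(y, cbind(`(Intercept)` = 1, x1 = x1, x2 = x2))
  ref <- stats::lm(y ~ x1 + x2)
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(f$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
})

test_that("panel models honour listwise deletion and the ART asymmetry", {
  b <- generate_cbo_panel(generator_config(seed = 23))
  adj <- adjust_scores(compute_scores(b$practice_matrix), b$context_table)
  fits <- fit_performance_models(adj, b$performance_panel)
  expect_named(fits, mgmtperf:::OUTCOME_INFO$outcome)
  expect_equal(fits$uc_art$n, 89L)
  expect_equal(fits$n_art$n, 89L)
  expect_equal(fits$uc_hts$n, 90L)
  expect_equal(fits$condoms_per_reached$n, 90L)
  # unit-cost designs carry the scale control, volume designs do not
  expect_true("scale" %in% names(fits$uc_art$coefficients))
  expect_false("scale" %in% names(fits$n_hts$coefficients))
  tab <- regression_table(fits)
  expect_equal(ncol(tab), 8L)
  expect_equal(tab$uc_art[tab$quantity == "n"], "89")
})

test_that("six-dimension model: orthogonal regressors reduce to univariable fits", {
  set.seed(41)
  n <- 60
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 6), n))))[, 2:7] * sqrt(n - 1)
  colnames(Q) <- mgmtperf:::DOMAIN_NAMES
  y <- drop(Q %*% c(1, -2, 0.5, 0, 3, 1)) + rnorm(n)
  multi <- fit_ols_robust(y, cbind(`(Intercept)` = 1, Q))
  for (d in colnames(Q)) {
    uni <- fit_ols_robust(y, cbind(`(Intercept)` = 1, Q[, d, drop = FALSE]))
    expect_equal(multi$coefficients[[d]], uni$coefficients[[d]],
                 tolerance = 1e-10)
  }
})

test_that("six-dimension model R2 is compared against the overall-score model", {
  hits <- 0L
  for (s in 1:10) {
    b <- generate_cbo_panel(generator_config(seed = 500 + s))
    adj <- adjust_scores(compute_scores(b$practice_matrix),
                         b$context_table)
    f6 <- fit_six_dimension_model(adj, b$performance_panel, "n_hts")
    f1 <- fit_performance_models(adj, b$performance_panel,
                                 outcomes = "n_hts")$n_hts
    if (f6$r_squared >= f1$r_squared - 1e-10) hits <- hits + 1L
  }
  # the models are not nested, but the 6-regressor span should win
  # essentially always
  expect_gte(hits, 9L)
})

test_that("error paths: rank deficiency, missing outcome, unmatched ids", {
  set.seed(1)
  x <- rnorm(10)
  expect_error(fit_ols_robust(rnorm(10), cbind(1, x, x)),
               class = "mgmtperf_collinearity_error")
  expect_error(fit_ols_robust(rep(NA_real_, 5), cbind(1, rnorm(5))),
               "no complete rows", class = "mgmtperf_data_error")
  b <- generate_cbo_panel(generator_config(seed = 2))
  adj <- adjust_scores(compute_scores(b$practice_matrix), b$context_table)
  expect_error(fit_performance_models(adj, b$performance_panel,
                                      outcomes = "nonexistent"),
               "nonexistent", class = "mgmtperf_data_error")
  panel2 <- b$performance_panel
  panel2$cbo_id[1] <- "CBO_XX"
  expect_error(fit_performance_models(adj, panel2),
               class = "mgmtperf_join_error")
})
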