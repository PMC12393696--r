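test_that("points on a line are interpolated at every quantile", {
  x <- seq(-2, 2, length.out = 9)
  y <- 3 - 1.5 * x
  for (q in c(0.25, 0.5, 0.75, 0.95)) {
    f <- suppressWarnings(fit_quantile(y, cbind(1, x), q))
    expect_equal(unname(f$coefficients), c(3, -1.5), tolerance = 1e-9)
    expect_equal(f$objective, 0, tolerance = 1e-10)
  }
})

test_that("six-point toys match exhaustive basic-solution search", {
  set.seed(19)
  for (rep in 1:25) {
    x <- rnorm(6); y <- 1 + x + rt(6, 2)
    X <- cbind(1, x)
    q <- sample(c(0.2, 0.35, 0.5, 0.65, 0.8), 1)
    f <- suppressWarnings(fit_quantile(y, X, q))
    oracle <- brute_force_qr(X, y, q)
    expect_equal(f$objective, oracle$objective, tolerance = 1e-9)
  }
})

test_that("check loss at the solution never exceeds the OLS line's", {
  set.seed(8)
  for (rep in 1:10) {
    n <- 40
    x <- rnorm(n); y <- 2 + x + rnorm(n) * (1 + 0.4 * abs(x))
    f <- suppressWarnings(fit_quantile(y, cbind(1, x), runif(1, .1, .9)))
    expect_lte(f$objective, f$ols_objective + 1e-10)
  }
})

test_that("no axis-aligned 1e-4 perturbation improves the objective", {
  set.seed(14)
  x <- rnorm(35); y <- 1 + 2 * x + rnorm(35)
  X <- cbind(1, x)
  for (q in c(0.25, 0.5, 0.9)) {
    f <- suppressWarnings(fit_quantile(y, X, q))
    for (j in 1:2) for (dlt in c(-1e-4, 1e-4)) {
      b2 <- f$coefficients; b2[j] <- b2[j] + dlt
      expect_gte(check_loss_r(y - drop(X %*% b2), q), f$objective - 1e-12)
    }
  }
})

test_that("median regression recovers the central line in large samples", {
  set.seed(42)
  n <- 2000
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n) # symmetric noise
  f <- fit_quantile(y, cbind(1, x), 0.5)
  expect_equal(unname(f$coefficients[2]), 2, tolerance = 0.05)
})

test_that("scale equivariance: scaling y scales the coefficients exactly", {
  set.seed(4)
  x <- rnorm(30); y <- 1 + x + rt(30, 3)
  f1 <- fit_quantile(y, cbind(1, x), 0.3)
  f2 <- fit_quantile(5 * y, cbind(1, x), 0.3)
  expect_equal(unname(f2$coefficients), 5 * unname(f1$coefficients),
               tolerance = 1e-8)
})

test_that("degenerate and small-tail inputs are flagged, not refused", {
  x <- rnorm(20)
  expect_warning(f <- fit_quantile(rep(3, 20), cbind(1, x), 0.5),
                 "degenerate")
  expect_equal(unname(f$coefficients), c(3, 0))
  # q95 at n = 90 leaves ~4.5 expected tail points
  set.seed(2)
  xx <- rnorm(90); yy <- 1 + xx + rnorm(90)
  expect_warning(f95 <- fit_quantile(yy, cbind(1, xx), 0.95), "tail")
  expect_true(f95$small_tail)
  f50 <- fit_quantile(yy, cbind(1, xx), 0.5)
  expect_false(f50$small_tail)
  expect_error(fit_quantile(yy, cbind(1, xx), 1.2), "strictly in",
               class = "mgmtperf_config_error")
})

test_that("quantile fits at the covariate mean are monotone in q", {
  set.seed(33)
  x <- rnorm(200); y <- 2 + x + rnorm(200)
  qs <- c(0.25, 0.5, 0.75, 0.95)
  preds <- sapply(qs, function(q) {
    f <- fit_quantile(y, cbind(1, x), q)
    sum(f$coefficients * c(1, mean(x)))
  })
  expect_true(all(diff(preds) > -1e-8))
})

test_that("bootstrap tests are seed-deterministic and symmetric in pair order", {
  set.seed(10)
  z <- rnorm(45); zz <- rep(z, 2)
  y <- 100 + 20 * zz + 30 * rnorm(90)
  X <- cbind(1, m = zz)
  r1 <- bootstrap_quantile_tests(y, X, c(0.25, 0.75), B = 150, seed = 77,
                                 coef = "m")
  r2 <- bootstrap_quantile_tests(y, X, c(0.25, 0.75), B = 150, seed = 77,
                                 coef = "m")
  expect_identical(r1$p_matrix, r2$p_matrix)
  expect_equal(r1$p_matrix["q25", "q75"], r1$p_matrix["q75", "q25"])
  r3 <- bootstrap_quantile_tests(y, X, c(0.25, 0.75), B = 150, seed = 78,
                                 coef = "m")
  expect_false(identical(r1$p_matrix, r3$p_matrix))
  expect_error(bootstrap_quantile_tests(y, X, c(0.25, 0.75), B = 50),
               "at least 100", class = "mgmtperf_config_error")
})

test_that("slope-gap power: the q25-vs-q95 test detects location-scale effects", {
  # scaled-down Monte Carlo (15 datasets); pre-measured power ~0.97
  rej <- 0L
  for (s in 1:15) {
    set.seed(s)
    z <- rnorm(45); zz <- rep(z, 2)
    y <- 10 + 2 * zz + (1 + 0.5 * zz) * 2 * rnorm(90)
    r <- suppressWarnings(bootstrap_quantile_tests(
      y, cbind(1, m = zz), c(0.25, 0.95), B = 200, seed = 600 + s,
      coef = "m"))
    if (r$tests$p_value[1] < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 15, 0.5)
})

test_that("quantile_table has the reporting shape and flags", {
  b <- generate_cbo_panel(generator_config(seed = 13))
  adj <- adjust_scores(compute_scores(b$practice_matrix), b$context_table)
  qt <- suppressWarnings(quantile_table(adj, b$performance_panel, B = 120,
                                        seed = 5,
                                        outcomes = c("uc_art", "n_hts")))
  tab <- qt$table
  expect_equal(nrow(tab), 8L)  # 2 outcomes x 4 quantiles
  expect_equal(tab$n[tab$outcome == "uc_art"], rep(89L, 4))
  expect_true(all(tab$small_tail[tab$q == 0.95]))
  # lower-triangular p-value block: q25 row has no p-values, q95 has three
  q25 <- tab[tab$q == 0.25, ]
  q95 <- tab[tab$q == 0.95, ]
  pcols <- c("p_vs_q25", "p_vs_q50", "p_vs_q75")
  expect_true(all(is.na(q25[, pcols])))
  expect_true(all(!is.na(q95[, pcols])))
  expect_true(all(q95[, pcols] >= 0 & q95[, pcols] <= 1))
  expect_error(suppressWarnings(quantile_table(adj, b$performance_panel,
                                               outcomes = "absent")),
               "absent", class = "mgmtperf_data_error")
})

test_that("true quantile slopes embedded by the generator are recovered in-sample", {
  # location-scale costs: slope should steepen with q per the stored truth
  cfg <- generator_config(seed = 55)
  b <- generate_cbo_panel(cfg)
  tr <- b$truth$true_quantile_slopes[, "uc_art"]
  expect_equal(unname(tr["q50"]), cfg$beta_true[["uc_art"]])
  expect_lt(tr[["q95"]], tr[["q25"]])  # negative scale coefficient
})
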