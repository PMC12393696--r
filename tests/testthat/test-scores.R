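test_that("z-scoring matches hand computation and drops degenerate items", {
  m <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 1, 1), d = c(0, 1, 0, 1))
  zs <- zscore_items(m)
  # sample SD of (1,1,0,0) is sqrt(1/3): z = +-0.8660254
  expect_equal(zs$z[, "a"], c(1, 1, -1, -1) * 0.5 / sqrt(1 / 3),
               tolerance = 1e-12)
  expect_equal(zs$dropped, "b")
  expect_equal(sort(zs$kept), c("a", "d"))
  expect_true(all(abs(colMeans(zs$z)) < 1e-12))
  expect_equal(unname(apply(zs$z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(zscore_items(m[1:2, ]), "at least 3",
               class = "mgmtperf_data_error")
})

test_that("GLS weights match explicit inverse-covariance arithmetic", {
  # items 1 and 2 correlated 0.8, item 3 independent; sample covariance
  # is exact by construction
  Sigma <- matrix(c(1, .8, 0, .8, 1, 0, 0, 0, 1), 3)
  Z <- exact_cov_block(20, Sigma, seed = 4)
  w <- gls_weights(Z)
  oracle <- rowSums(solve(Sigma)) / sum(solve(Sigma))
  expect_equal(w$weights, unname(oracle), tolerance = 1e-10)
  # the independent item outweighs each redundant one
  expect_gt(w$weights[3], w$weights[1])
  expect_equal(w$weights[3], 0.9 / 1.9, tolerance = 1e-10)
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  expect_false(w$regularization_used)
})

test_that("GLS edge cases: single item, identity covariance, 4-item oracle", {
  z1 <- matrix(rnorm(10), dimnames = list(NULL, "only"))
  w1 <- gls_weights(z1)
  expect_equal(w1$weights, 1)
  # exactly uncorrelated unit-variance items -> equal weights
  Z <- exact_cov_block(15, diag(4), seed = 2)
  expect_equal(gls_weights(Z)$weights, rep(0.25, 4), tolerance = 1e-10)
  # random 4-item block vs brute-force inversion of the sample covariance
  set.seed(8)
  Zr <- scale(matrix(rnorm(60), 15, 4))
  wr <- gls_weights(Zr)
  S <- cov(Zr)
  expect_equal(wr$weights, unname(rowSums(solve(S)) / sum(solve(S))),
               tolerance = 1e-10)
})

test_that("singular covariance triggers recorded ridge or a clear error", {
  Z <- matrix(rnorm(20), 10, 2)
  Z <- cbind(Z, Z[, 1])  # exact duplicate
  colnames(Z) <- c("a", "b", "c")
  Z <- scale(Z)
  expect_error(gls_weights(Z, ridge = "none"), "singular",
               class = "mgmtperf_numeric_error")
  w <- gls_weights(Z)
  expect_true(w$regularization_used)
  expect_gt(w$ridge, 0)
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
})

test_that("seven scores: standardized, both overall modes, canonical layout", {
  b <- generate_cbo_panel(generator_config(seed = 14))
  for (mode in c("domains", "items")) {
    sc <- compute_scores(b$practice_matrix, overall_mode = mode)
    expect_equal(ncol(sc$domain_scores), 6L)
    expect_true(all(abs(colMeans(sc$domain_scores)) < 1e-10))
    expect_true(all(abs(apply(sc$domain_scores, 2, sd) - 1) < 1e-10))
    expect_equal(mean(sc$overall_score), 0, tolerance = 1e-10)
    expect_equal(sd(sc$overall_score), 1, tolerance = 1e-10)
  }
  # all-items mode must regularize the rank-deficient 67-item covariance
  sc_items <- compute_scores(b$practice_matrix, overall_mode = "items")
  expect_true(sc_items$weightings$overall$regularization_used)
})

test_that("equal-variance independent items reduce to the rescaled mean z-score", {
  Z <- exact_cov_block(24, diag(5), seed = 9)
  w <- gls_weights(Z)
  s_gls <- drop(Z %*% w$weights)
  expect_equal(cor(s_gls, rowMeans(Z)), 1, tolerance = 1e-10)
})

test_that("replication invariance: duplicating every CBO preserves scores up to
          the n-1 standardization factor", {
  # sample-SD standardization (n - 1 denominator, as specified for the
  # item z-scores) rescales all scores of the duplicated sample by the
  # common factor sqrt((2n - 1) / (2n - 2)) x ...; the scores are exactly
  # proportional, with every CBO's duplicate agreeing with the original
  pm <- toy_practice_matrix(n = 15, seed = 5)
  sc1 <- compute_scores(pm)
  pm2 <- practice_matrix(rbind(pm$items, pm$items), pm$domain_map,
                         c(pm$cbo_ids, paste0(pm$cbo_ids, "_dup")))
  sc2 <- compute_scores(pm2)
  expect_equal(unname(sc2$domain_scores[1:15, ]),
               unname(sc2$domain_scores[16:30, ]), tolerance = 1e-10)
  for (d in colnames(sc1$domain_scores)) {
    expect_equal(as.numeric(scale(sc2$domain_scores[1:15, d])),
                 as.numeric(scale(sc1$domain_scores[, d])),
                 tolerance = 1e-8)
  }
  expect_equal(as.numeric(scale(sc2$overall_score[1:15])),
               as.numeric(scale(sc1$overall_score)), tolerance = 1e-8)
})

test_that("affine invariance: a + b*x item transforms leave scores unchanged", {
  pm <- toy_practice_matrix(n = 20, seed = 3)
  base <- mgmtperf:::score_matrix(pm$items, pm$domain_map)
  items2 <- pm$items
  items2[, 2] <- 3 + 2.5 * items2[, 2]
  items2[, 7] <- -1 + 0.4 * items2[, 7]
  shifted <- mgmtperf:::score_matrix(items2, pm$domain_map)
  expect_equal(shifted$domain_scores, base$domain_scores, tolerance = 1e-10)
  expect_equal(shifted$overall, base$overall, tolerance = 1e-10)
})

test_that("flipping an item 0 -> 1 never lowers that CBO's domain score
          (non-negative correlations and weights)", {
  # The unconditional claim is false: inverse-covariance weights can be
  # negative even when all pairwise correlations are non-negative. The
  # property is asserted on the cases where the weighting is monotone.
  tested <- 0L
  for (s in 1:12) {
    b <- generate_cbo_panel(generator_config(seed = 300 + s))
    pm <- b$practice_matrix
    sc <- compute_scores(pm)
    zb <- zscore_items(pm)
    for (d in unique(pm$domain_map)) {
      cols <- names(pm$domain_map)[pm$domain_map == d]
      kept <- intersect(cols, zb$kept)
      if (any(cor(zb$z[, kept]) < 0) ||
          any(sc$weightings[[d]]$weights < 0)) next
      idx <- which(pm$items[, cols] == 0, arr.ind = TRUE)
      if (!nrow(idx)) next
      i <- idx[1, 1]; j <- cols[idx[1, 2]]
      pm2 <- pm; pm2$items[i, j] <- 1
      sc2 <- compute_scores(pm2)
      zb2 <- zscore_items(pm2)
      if (any(cor(zb2$z[, intersect(cols, zb2$kept)]) < 0) ||
          any(sc2$weightings[[d]]$weights < 0)) next
      tested <- tested + 1L
      expect_gte(sc2$domain_scores[i, d], sc$domain_scores[i, d] - 1e-10)
    }
  }
  expect_gt(tested, 5L)
})

test_that("a fully degenerate domain is refused by name", {
  pm <- toy_practice_matrix(n = 10, seed = 2)
  cols <- names(pm$domain_map)[pm$domain_map == "community_engagement"]
  pm$items[, cols] <- 1
  expect_error(compute_scores(pm), "community_engagement",
               class = "mgmtperf_domain_error")
})

test_that("practice_matrix validates coding, ids and the domain map", {
  m <- matrix(c(0, 1, 2, 0), 2, dimnames = list(NULL, c("a", "b")))
  expect_error(practice_matrix(m, c(a = "target_setting",
                                    b = "target_setting")),
               "non-binary", class = "mgmtperf_parse_error")
  m2 <- matrix(0:1, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(practice_matrix(m2, c(a = "target_setting",
                                     b = "target_setting"),
                               cbo_ids = c("x", "x")),
               "duplicate", class = "mgmtperf_parse_error")
  expect_error(practice_matrix(m2, c(a = "target_setting")),
               "missing from domain map", class = "mgmtperf_parse_error")
  expect_error(practice_matrix(m2, c(a = "target_setting", b = "nope")),
               "unknown domains", class = "mgmtperf_parse_error")
})
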