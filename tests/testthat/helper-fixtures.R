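# Shared fixtures and independent oracles used across the suite.

OUTS <- c("uc_art", "uc_hts", "uc_sti", "n_art", "n_hts", "n_sti",
          "condoms_per_reached")

# Calibration world for parameter-recovery tests: all outcomes share one
# intercept/effect/noise scale so that floors and integer rounding almost
# never bind and the linear model is exactly correctly specified. Chosen a
# priori (see the methods vignette): effect 100 = 0.4 x noise SD keeps
# score-measurement attenuation small against the sampling SE at n = 90.
calib_config <- function(seed, beta = 100, latent_loading = 1.2) {
  generator_config(
    latent_loading = latent_loading,
    outcome_mean = stats::setNames(rep(1000, 7), OUTS),
    beta_true = stats::setNames(rep(beta, 7), OUTS),
    noise_sd = stats::setNames(rep(250, 7), OUTS),
    quantile_scale = stats::setNames(rep(0, 7), OUTS),
    seed = seed)
}

# Tiny practice matrix with a handful of items per domain.
toy_practice_matrix <- function(n = 12, seed = 1, items_per_domain = 2) {
  set.seed(seed)
  counts <- stats::setNames(rep(items_per_domain, 6),
                            mgmtperf:::DOMAIN_NAMES)
  nm <- unlist(lapply(names(counts), function(d)
    sprintf("%s_item%02d", d, seq_len(counts[[d]]))))
  z <- rnorm(n)
  m <- sapply(seq_along(nm), function(j) rbinom(n, 1, plogis(z)))
  colnames(m) <- nm
  # guard against degenerate columns in tiny samples
  for (j in seq_len(ncol(m))) {
    if (length(unique(m[, j])) == 1L) m[1:2, j] <- c(0, 1)
  }
  practice_matrix(m, stats::setNames(rep(names(counts), counts), nm),
                  sprintf("CBO_%02d", seq_len(n)))
}

# A matrix whose sample covariance is exactly Sigma: orthonormalize
# centered Gaussian columns, then color by chol(Sigma).
exact_cov_block <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  k <- ncol(Sigma)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * k), n))))[, 2:(k + 1), drop = FALSE]
  Z <- sqrt(n - 1) * Q %*% chol(Sigma)
  colnames(Z) <- paste0("it", seq_len(k))
  Z
}

check_loss_r <- function(r, q) sum(r * (q - (r < 0)))

# Brute-force quantile regression: enumerate all p-point interpolating
# solutions (independent of the package's solver).
brute_force_qr <- function(X, y, q) {
  n <- length(y); p <- ncol(X)
  best <- NULL; best_obj <- Inf
  for (h in utils::combn(n, p, simplify = FALSE)) {
    Xh <- X[h, , drop = FALSE]
    if (abs(det(Xh)) < 1e-10) next
    b <- solve(Xh, y[h])
    obj <- check_loss_r(y - drop(X %*% b), q)
    if (obj < best_obj) { best_obj <- obj; best <- b }
  }
  list(coef = best, objective = best_obj)
}

# Brute-force Shapley: average sequential R-squared gains over all
# orderings, fitting with stats::lm (independent of shapley_r2).
brute_force_shapley <- function(y, players, fixed = NULL) {
  p <- length(players)
  perms <- gtools_permutations(p)
  r2_of <- function(blocks) {
    if (length(blocks) == 0L && is.null(fixed)) return(0)
    X <- do.call(cbind, c(list(fixed), blocks))
    if (is.null(X)) return(0)
    summary(stats::lm(y ~ X))$r.squared
  }
  contrib <- stats::setNames(numeric(p), names(players))
  for (r in seq_len(nrow(perms))) {
    prev <- list()
    for (j in perms[r, ]) {
      before <- r2_of(prev)
      prev <- c(prev, players[j])
      after <- r2_of(prev)
      contrib[names(players)[j]] <- contrib[names(players)[j]] +
        (after - before) / nrow(perms)
    }
  }
  contrib
}

# All permutations of 1..n without extra packages.
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}
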