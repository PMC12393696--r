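#' Quantile regression fit
#'
#' Estimates the conditional quantile function \eqn{Q_q(y \mid x) = x'\gamma}
#' by minimizing the check loss \eqn{\sum_i \rho_q(y_i - x_i'\gamma)} with
#' \eqn{\rho_q(u) = u\,(q - 1\{u < 0\})}. The solver runs iteratively
#' reweighted least squares on the smoothed objective and then polishes the
#' solution over exact interpolating (basic) fits, with a deterministic
#' tie-break, so the returned coefficients attain the piecewise-linear
#' optimum. Asymptotic standard errors use the iid kernel-sparsity estimate
#' with the Hall-Sheather bandwidth.
#'
#' @param y outcome vector.
#' @param X design matrix including the intercept column.
#' @param q quantile level in (0, 1).
#' @param tail_warn_points flag the fit as small-tail when the expected
#'   number of observations in the short tail, \eqn{n \min(q, 1-q)}, falls
#'   below this many points (default 5; at n = 90 the 95th percentile
#'   leaves about 4.5 tail points and is flagged).
#' @return an object of class \code{mgmt_quantile_fit}: \code{coefficients}
#'   (named by design column), \code{se} (asymptotic), \code{q}, \code{n},
#'   \code{objective} (check loss at the solution), \code{ols_objective}
#'   (check loss of the OLS line, an upper bound), \code{small_tail},
#'   \code{degenerate}.
#' @export
fit_quantile <- function(y, X, q, tail_warn_points = 5) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop_mgmt("quantile level q must lie strictly in (0, 1)",
              class = "mgmtperf_config_error")
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  ok <- complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p)
    stop_mgmt("quantile fit needs n (%d) > parameters (%d)", n, p,
              class = "mgmtperf_data_error")
  small_tail <- n * min(q, 1 - q) < tail_warn_points
  if (small_tail)
    warning(sprintf(
      "q = %.2f leaves ~%.1f expected tail points at n = %d; estimates are fragile",
      q, n * min(q, 1 - q), n), call. = FALSE)
  degenerate <- FALSE
  if (sd(y) == 0) {
    degenerate <- TRUE
    warning("degenerate outcome (all values equal): zero-slope fit",
            call. = FALSE)
    beta <- c(y[1], rep(0, p - 1L))
  } else {
    beta <- .qr_fit_cpp(X, y, q)
    if (anyNA(beta))
      stop_mgmt("quantile fit failed to converge at q = %.2f", q,
                class = "mgmtperf_numeric_error")
  }
  names(beta) <- colnames(X)
  resid <- y - drop(X %*% beta)
  obj <- .qr_objective_cpp(X, y, beta, q)
  b_ols <- qr.coef(qr(X), y)
  obj_ols <- .qr_objective_cpp(X, y, b_ols, q)

  # iid sparsity SE: s(q) = 1/f(F^{-1}(q)) from a difference quotient of
  # empirical residual quantiles at the Hall-Sheather bandwidth.
  h <- qnorm(0.975)^(2 / 3) *
    (1.5 * dnorm(qnorm(q))^2 / (2 * qnorm(q)^2 + 1))^(1 / 3) * n^(-1 / 3)
  lo <- max(q - h, 1 / (n + 1)); hi <- min(q + h, n / (n + 1))
  spars <- diff(quantile(resid, c(lo, hi), names = FALSE, type = 7)) /
    (hi - lo)
  V <- q * (1 - q) * spars^2 * chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(V))
  names(se) <- colnames(X)

  structure(list(coefficients = beta, se = se, q = q, n = n,
                 objective = obj, ols_objective = obj_ols,
                 small_tail = small_tail, degenerate = degenerate),
            class = "mgmt_quantile_fit")
}

#' @export
print.mgmt_quantile_fit <- function(x, ...) {
  cat(sprintf("<mgmt_quantile_fit> q = %.2f, n = %d, check loss = %.4f%s\n",
              x$q, x$n, x$objective,
              if (x$small_tail) " [small tail]" else ""))
  print(round(rbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Paired-bootstrap inference across quantiles
#'
#' Resamples rows with replacement, refits every requested quantile on each
#' resample, and tests the equality of the management coefficient across
#' quantile pairs. For a pair \eqn{(q_a, q_b)} the statistic is the
#' full-sample coefficient difference divided by the bootstrap SD of the
#' replicate differences, referred to the standard normal (Wald); a
#' percentile-interval p-value is available as an option. Per-quantile
#' bootstrap SEs are reported alongside.
#'
#' @param y outcome vector.
#' @param X design matrix with intercept.
#' @param quantiles vector of quantile levels.
#' @param B bootstrap replicates (default 500, at least 100).
#' @param seed integer seed for the resampling.
#' @param coef name or index of the tested coefficient (default the second
#'   design column, the management score).
#' @param method \code{"wald"} (default) or \code{"percentile"}.
#' @param max_fail_rate abort if more than this share of replicate fits
#'   fail (default 0.1).
#' @return list with \code{fits} (per-quantile \code{mgmt_quantile_fit}),
#'   \code{boot_se} (per-quantile bootstrap SE of the coefficient),
#'   \code{tests} (data frame: qa, qb, difference, se, p_value),
#'   \code{p_matrix} (symmetric matrix of p-values), \code{B},
#'   \code{n_failed}, \code{seed}.
#' @export
bootstrap_quantile_tests <- function(y, X, quantiles, B = 500L, seed = 1L,
                                     coef = 2L,
                                     method = c("wald", "percentile"),
                                     max_fail_rate = 0.1) {
  method <- match.arg(method)
  if (B < 100L)
    stop_mgmt("B must be at least 100 (got %d)", B,
              class = "mgmtperf_config_error")
  if (any(quantiles <= 0 | quantiles >= 1))
    stop_mgmt("quantiles must lie strictly in (0, 1)",
              class = "mgmtperf_config_error")
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  ok <- complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  ci <- if (is.character(coef)) match(coef, colnames(X)) else as.integer(coef)
  if (is.na(ci) || ci < 1L || ci > p)
    stop_mgmt("tested coefficient not found in design",
              class = "mgmtperf_config_error")

  fits <- lapply(quantiles, function(q)
    suppressWarnings(fit_quantile(y, X, q)))
  names(fits) <- sprintf("q%02d", round(quantiles * 100))
  est <- vapply(fits, function(f) f$coefficients[ci], numeric(1))

  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B)
  reps <- .qr_boot_cpp(X, y, quantiles, idx)
  # replicate coefficient matrix: B x n_quantiles
  coefs <- reps[, (seq_along(quantiles) - 1L) * p + ci, drop = FALSE]
  colnames(coefs) <- names(fits)
  failed <- !stats::complete.cases(coefs)
  if (mean(failed) > max_fail_rate)
    stop_mgmt("bootstrap failure rate %.1f%% exceeds %.0f%%",
              100 * mean(failed), 100 * max_fail_rate,
              class = "mgmtperf_numeric_error")
  coefs_ok <- coefs[!failed, , drop = FALSE]
  boot_se <- apply(coefs_ok, 2L, sd)

  pairs <- utils::combn(seq_along(quantiles), 2L)
  tests <- data.frame(qa = quantiles[pairs[1, ]], qb = quantiles[pairs[2, ]],
                      difference = NA_real_, se = NA_real_,
                      p_value = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d_reps <- coefs_ok[, a] - coefs_ok[, b]
    d_hat <- est[a] - est[b]
    se_d <- sd(d_reps)
    tests$difference[i] <- d_hat
    tests$se[i] <- se_d
    tests$p_value[i] <- if (method == "wald") {
      if (se_d > 0) 2 * pnorm(-abs(d_hat) / se_d) else as.numeric(d_hat == 0)
    } else {
      2 * min(mean(d_reps <= 0), mean(d_reps >= 0))
    }
  }
  pm <- matrix(NA_real_, length(quantiles), length(quantiles),
               dimnames = list(names(fits), names(fits)))
  for (i in seq_len(ncol(pairs))) {
    pm[pairs[1, i], pairs[2, i]] <- tests$p_value[i]
    pm[pairs[2, i], pairs[1, i]] <- tests$p_value[i]
  }
  list(fits = fits, estimates = est, boot_se = boot_se, tests = tests,
       p_matrix = pm, B = B, n_failed = sum(failed), seed = seed)
}

#' Quantile-regression report across all outcomes
#'
#' For every performance indicator, fits the management quantile model at
#' the requested percentiles (intercept + overall adjusted score, plus the
#' intervention scale control for unit costs), bootstraps all quantiles on
#' shared resamples, and reports the coefficient, its bootstrap SE, the
#' sample size, and the lower-triangular block of cross-quantile equality
#' p-values.
#'
#' @param adjusted an \code{mgmt_adjusted_scores} object.
#' @param panel performance panel data frame.
#' @param quantiles quantile levels (default 0.25, 0.50, 0.75, 0.95).
#' @param B bootstrap replicates (default 500).
#' @param seed integer seed.
#' @param use_scale include scale control in unit-cost models.
#' @param outcomes outcome subset.
#' @return list with \code{table} (long data frame: outcome, q, estimate,
#'   boot_se, n, p-value columns vs lower quantiles) and \code{detail}
#'   (per-outcome bootstrap results).
#' @export
quantile_table <- function(adjusted, panel,
                           quantiles = c(0.25, 0.50, 0.75, 0.95),
                           B = 500L, seed = 1L, use_scale = TRUE,
                           outcomes = OUTCOME_INFO$outcome) {
  idx <- join_scores_panel(adjusted, panel)
  mgmt <- adjusted$adjusted[idx, "overall"]
  detail <- list()
  rows <- list()
  qlab <- sprintf("q%02d", round(quantiles * 100))
  for (o in outcomes) {
    if (!o %in% names(panel))
      stop_mgmt("outcome '%s' not present in panel", o,
                class = "mgmtperf_data_error")
    yo <- panel[[o]]
    if (all(is.na(yo)))
      stop_mgmt("outcome '%s' has no observed values", o,
                class = "mgmtperf_data_error")
    X <- cbind(`(Intercept)` = 1, management = mgmt)
    info <- OUTCOME_INFO[OUTCOME_INFO$outcome == o, ]
    if (use_scale && nrow(info) && !is.na(info$scale))
      X <- cbind(X, scale = panel[[info$scale]])
    bt <- bootstrap_quantile_tests(yo, X, quantiles, B = B,
                                   seed = derive_seed(seed, match(o,
                                     OUTCOME_INFO$outcome)),
                                   coef = "management")
    detail[[o]] <- bt
    df <- data.frame(outcome = o, q = quantiles,
                     estimate = unname(bt$estimates),
                     boot_se = unname(bt$boot_se),
                     n = vapply(bt$fits, function(f) f$n, integer(1)),
                     small_tail = vapply(bt$fits, function(f) f$small_tail,
                                         logical(1)))
    for (j in seq_along(quantiles)[-length(quantiles)]) {
      col <- paste0("p_vs_", qlab[j])
      df[[col]] <- NA_real_
      for (i in seq_along(quantiles)) {
        if (i > j) df[[col]][i] <- bt$p_matrix[i, j]
      }
    }
    rows[[o]] <- df
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       detail = detail, quantiles = quantiles, B = B, seed = seed)
}
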