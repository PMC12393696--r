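#' OLS with heteroskedasticity-robust standard errors
#'
#' Least-squares fit with a sandwich covariance \eqn{(X'X)^{-1} X'
#' \mathrm{diag}(w_i e_i^2) X (X'X)^{-1}}. The default HC1 flavour applies
#' the small-sample factor \eqn{n/(n-k)} to the squared residuals; HC0 uses
#' the raw residuals, HC2 divides by \eqn{1-h_i}, HC3 by \eqn{(1-h_i)^2},
#' with \eqn{h_i} the leverage. Rows with missing values in \code{y} or
#' \code{X} are dropped listwise and counted.
#'
#' @param y numeric outcome vector.
#' @param X design matrix including the intercept column.
#' @param hc_type one of "HC0", "HC1", "HC2", "HC3" (default "HC1").
#' @param outcome optional outcome label carried into the result.
#' @return an object of class \code{mgmt_ols_fit}: coefficients, robust
#'   \code{se}, \code{t}, \code{p_value} (two-sided on n-k df), \code{n},
#'   \code{df_residual}, \code{r_squared}, robust Wald \code{f_statistic}
#'   with \code{f_p_value} (slopes jointly zero), \code{vcov},
#'   \code{fitted}, \code{residuals}, \code{hc_type}, \code{n_dropped}.
#' @examples
#' x <- c(0, 1, 2, 3); y <- c(1, 2, 2, 4)
#' fit <- fit_ols_robust(y, cbind(1, x))
#' fit$coefficients; fit$se
#' @export
fit_ols_robust <- function(y, X, hc_type = c("HC1", "HC0", "HC2", "HC3"),
                           outcome = NULL) {
  hc_type <- match.arg(hc_type)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  ok <- complete.cases(y, X)
  n_dropped <- sum(!ok)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); k <- ncol(X)
  if (n == 0L)
    stop_mgmt("outcome '%s': no complete rows", outcome %||% "y",
              class = "mgmtperf_data_error")
  if (n <= k)
    stop_mgmt("outcome '%s': %d rows for %d parameters", outcome %||% "y",
              n, k, class = "mgmtperf_data_error")
  qx <- qr(X)
  if (qx$rank < k)
    stop_mgmt("outcome '%s': design is rank deficient (column '%s')",
              outcome %||% "y", colnames(X)[qx$pivot[qx$rank + 1L]],
              class = "mgmtperf_collinearity_error")
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  e <- y - fitted
  XtX_inv <- chol2inv(qr.R(qx))
  h <- rowSums((X %*% XtX_inv) * X)         # leverages
  w <- switch(hc_type,
              HC0 = rep(1, n),
              HC1 = rep(n / (n - k), n),
              HC2 = 1 / (1 - h),
              HC3 = 1 / (1 - h)^2)
  meat <- crossprod(X * (w * e^2), X)
  V <- XtX_inv %*% meat %*% XtX_inv
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - k)
  ybar <- mean(y)
  tss <- sum((y - ybar)^2)
  r2 <- if (tss > 0) 1 - sum(e^2) / tss else NA_real_
  # Robust Wald test that all non-intercept coefficients are zero.
  slope_idx <- which(colnames(X) != "(Intercept)")
  f_stat <- f_p <- NA_real_
  if (length(slope_idx)) {
    b1 <- beta[slope_idx]
    V1 <- V[slope_idx, slope_idx, drop = FALSE]
    wald <- tryCatch(drop(t(b1) %*% solve(V1, b1)), error = function(e) NA)
    f_stat <- wald / length(slope_idx)
    f_p <- pf(f_stat, length(slope_idx), n - k, lower.tail = FALSE)
  }
  structure(list(outcome = outcome, coefficients = beta, se = se, t = tval,
                 p_value = pval, n = n, n_dropped = n_dropped,
                 df_residual = n - k, r_squared = r2,
                 f_statistic = f_stat, f_p_value = f_p, vcov = V,
                 fitted = fitted, residuals = e, hc_type = hc_type),
            class = "mgmt_ols_fit")
}

#' @export
print.mgmt_ols_fit <- function(x, ...) {
  cat(sprintf("<mgmt_ols_fit>%s n = %d, R2 = %.3f, %s\n",
              if (!is.null(x$outcome)) paste0(" ", x$outcome, ":") else "",
              x$n, x$r_squared, x$hc_type))
  tab <- cbind(Estimate = x$coefficients, `Robust SE` = x$se,
               t = x$t, `p` = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

# Join the overall (or domain) adjusted scores onto the panel rows.
join_scores_panel <- function(adjusted, panel) {
  if (!inherits(adjusted, "mgmt_adjusted_scores"))
    stop_mgmt("expected an mgmt_adjusted_scores object",
              class = "mgmtperf_data_error")
  idx <- match(panel$cbo_id, adjusted$cbo_ids)
  if (anyNA(idx)) {
    miss <- unique(panel$cbo_id[is.na(idx)])
    stop_mgmt("%d panel rows reference CBOs without scores (e.g. %s)",
              sum(is.na(idx)), miss[1], class = "mgmtperf_join_error")
  }
  idx
}

#' Fit the seven per-outcome performance models
#'
#' For each performance indicator, fits outcome ~ intercept + overall
#' adjusted management score by robust OLS. The three unit-cost models
#' additionally control for the scale of services provided in the matching
#' intervention, the usual adjustment when modelling unit costs. Missing
#' outcome values are dropped listwise per model, so sample sizes can
#' differ across outcomes (e.g. 89 complete ART rows vs 90 for the others).
#'
#' @param adjusted an \code{mgmt_adjusted_scores} object.
#' @param panel performance panel data frame.
#' @param hc_type robust-covariance flavour (default "HC1").
#' @param use_scale include the per-intervention scale control in unit-cost
#'   models (default TRUE).
#' @param outcomes subset of outcome names (default all seven).
#' @return list of \code{mgmt_ols_fit}, named by outcome, with class
#'   \code{mgmt_fit_set}.
#' @export
fit_performance_models <- function(adjusted, panel, hc_type = "HC1",
                                   use_scale = TRUE,
                                   outcomes = OUTCOME_INFO$outcome) {
  idx <- join_scores_panel(adjusted, panel)
  mgmt <- adjusted$adjusted[idx, "overall"]
  fits <- list()
  for (o in outcomes) {
    if (!o %in% names(panel))
      stop_mgmt("outcome '%s' not present in panel", o,
                class = "mgmtperf_data_error")
    info <- OUTCOME_INFO[OUTCOME_INFO$outcome == o, ]
    X <- cbind(`(Intercept)` = 1, management = mgmt)
    if (use_scale && nrow(info) && !is.na(info$scale))
      X <- cbind(X, scale = panel[[info$scale]])
    fits[[o]] <- fit_ols_robust(panel[[o]], X, hc_type = hc_type,
                                outcome = o)
  }
  structure(fits, class = "mgmt_fit_set")
}

#' Fit the six-dimension model for one outcome
#'
#' Regresses a performance indicator on the six adjusted domain scores
#' jointly (plus the intervention scale control for unit costs). This model
#' is the input surface for the Shapley decomposition of explained
#' variance.
#'
#' @inheritParams fit_performance_models
#' @param outcome one outcome column name.
#' @return an \code{mgmt_ols_fit} whose design carries the six domain
#'   columns (and optional scale column).
#' @export
fit_six_dimension_model <- function(adjusted, panel, outcome,
                                    hc_type = "HC1", use_scale = TRUE) {
  idx <- join_scores_panel(adjusted, panel)
  if (!outcome %in% names(panel))
    stop_mgmt("outcome '%s' not present in panel", outcome,
              class = "mgmtperf_data_error")
  doms <- colnames(adjusted$adjusted)
  doms <- doms[doms != "overall"]
  X <- cbind(`(Intercept)` = 1, adjusted$adjusted[idx, doms, drop = FALSE])
  info <- OUTCOME_INFO[OUTCOME_INFO$outcome == outcome, ]
  if (use_scale && nrow(info) && !is.na(info$scale))
    X <- cbind(X, scale = panel[[info$scale]])
  fit_ols_robust(panel[[outcome]], X, hc_type = hc_type, outcome = outcome)
}

#' Table of per-outcome regression results
#'
#' Arranges a fit set into the conventional report: management coefficient
#' and robust SE, intercept and robust SE, significance stars, N, and the
#' robust Wald F p-value, one column per performance indicator.
#'
#' @param fits an \code{mgmt_fit_set} from
#'   \code{\link{fit_performance_models}}.
#' @return data frame, one row per reported quantity.
#' @export
regression_table <- function(fits) {
  stars <- function(p) if (is.na(p)) "" else if (p < 0.001) "***" else
    if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  cols <- lapply(fits, function(f) {
    b <- f$coefficients
    c(management = sprintf("%.2f%s", b[["management"]],
                           stars(f$p_value[["management"]])),
      management_se = sprintf("(%.2f)", f$se[["management"]]),
      intercept = sprintf("%.2f%s", b[["(Intercept)"]],
                          stars(f$p_value[["(Intercept)"]])),
      intercept_se = sprintf("(%.2f)", f$se[["(Intercept)"]]),
      n = as.character(f$n),
      f_statistic = sprintf("%.2f", f$f_statistic),
      f_p_value = ifelse(f$f_p_value < 0.001, "<0.001",
                         sprintf("%.3f", f$f_p_value)))
  })
  out <- data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- names(fits)
  cbind(quantity = rownames(out), out, row.names = NULL)
}
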