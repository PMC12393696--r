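#' Build the contextual design matrix
#'
#' Assembles the regression design used to adjust management scores for
#' context: an intercept plus country indicator, manager-education
#' indicator, years since the CBO opened, staff count, and the number of
#' competitor CBOs within a 30-minute driving radius.
#'
#' @param context data frame with \code{cbo_id} and the five contextual
#'   covariates.
#' @param covariates character vector naming the covariate columns to use
#'   (defaults to all five).
#' @return list with \code{cbo_ids} and \code{X} (n x (p+1) matrix with
#'   intercept), checked for full column rank.
#' @export
context_matrix <- function(context, covariates = CONTEXT_COVARIATES) {
  miss <- setdiff(c("cbo_id", covariates), names(context))
  if (length(miss))
    stop_mgmt("context table missing columns: %s",
              paste(miss, collapse = ", "), class = "mgmtperf_data_error")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(context[covariates]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_mgmt("context design is rank deficient; dependent columns: %s",
              paste(dep, collapse = ", "),
              class = "mgmtperf_collinearity_error")
  }
  list(cbo_ids = as.character(context$cbo_id), X = X)
}

#' Adjust management scores for contextual characteristics
#'
#' Regresses each of the seven management scores on the contextual
#' covariates by OLS (robust standard errors reported on each fit) and
#' returns the adjusted scores. Two readings of "adjusted" are supported:
#' \code{mode = "residual"} (the default) takes the part of each score
#' orthogonal to context; \code{mode = "fitted"} takes the conditional
#' expectation given context, i.e. the fitted values \eqn{X\hat\beta}. The
#' two modes decompose the crude score exactly: fitted + residual = crude,
#' and in either mode the adjusted score has variance no larger than the
#' crude score. Residual is the default because fitted-mode scores are, by
#' construction, linear combinations of the same context design: the six
#' fitted domain scores span at most the context column space, so any
#' multi-dimension model on them (and its Shapley decomposition) is rank
#' deficient. Only the residual reading yields an identifiable
#' six-dimension model.
#'
#' @param scores an \code{mgmt_scores} object.
#' @param context a context data frame or the result of
#'   \code{\link{context_matrix}}.
#' @param mode \code{"residual"} or \code{"fitted"}.
#' @param restandardize if TRUE, re-scale each adjusted score to mean 0,
#'   SD 1 (recorded in the result; default FALSE).
#' @param hc_type robust-covariance flavour for the per-score fits.
#' @return an object of class \code{mgmt_adjusted_scores}: \code{cbo_ids},
#'   \code{adjusted} (CBO x 7 matrix, columns = six domains + overall),
#'   \code{crude}, \code{mode}, \code{adjustment_fits}, \code{restandardized}.
#' @export
adjust_scores <- function(scores, context, mode = c("residual", "fitted"),
                          restandardize = FALSE, hc_type = "HC1") {
  mode <- match.arg(mode)
  if (!inherits(scores, "mgmt_scores"))
    stop_mgmt("adjust_scores expects an mgmt_scores object",
              class = "mgmtperf_data_error")
  cm <- if (is.list(context) && !is.data.frame(context) &&
            !is.null(context$X)) context else context_matrix(context)
  idx <- match(scores$cbo_ids, cm$cbo_ids)
  if (anyNA(idx))
    stop_mgmt("context rows missing for %d CBOs (first: %s)",
              sum(is.na(idx)), scores$cbo_ids[which(is.na(idx))[1]],
              class = "mgmtperf_join_error")
  X <- cm$X[idx, , drop = FALSE]
  if (nrow(X) <= ncol(X))
    stop_mgmt("need more CBOs (%d) than context parameters (%d)",
              nrow(X), ncol(X), class = "mgmtperf_data_error")
  crude <- cbind(scores$domain_scores, overall = scores$overall_score)
  fits <- list()
  adjusted <- matrix(NA_real_, nrow(crude), ncol(crude),
                     dimnames = dimnames(crude))
  for (j in colnames(crude)) {
    fit <- fit_ols_robust(crude[, j], X, hc_type = hc_type, outcome = j)
    fits[[j]] <- fit
    adjusted[, j] <- if (mode == "fitted") fit$fitted else fit$residuals
  }
  if (restandardize) adjusted <- apply(adjusted, 2L, function(x)
    as.numeric(scale(x)))
  rownames(adjusted) <- scores$cbo_ids
  structure(list(cbo_ids = scores$cbo_ids, adjusted = adjusted,
                 crude = crude, mode = mode, adjustment_fits = fits,
                 restandardized = restandardize),
            class = "mgmt_adjusted_scores")
}

#' @export
print.mgmt_adjusted_scores <- function(x, ...) {
  cat(sprintf("<mgmt_adjusted_scores> %d CBOs, mode = %s%s\n",
              length(x$cbo_ids), x$mode,
              if (x$restandardized) " (restandardized)" else ""))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of crude vs adjusted scores
#'
#' Computes the raw two-sample KS statistic \eqn{D = \sup_x |F_1(x) -
#' F_2(x)|} over the pooled sample, the scaled statistic \eqn{T =
#' \sqrt{n_1 n_2 / (n_1 + n_2)}\, D} used by the asymptotic test, and the
#' asymptotic two-sided p-value \eqn{p = 2\sum_{k\ge1} (-1)^{k-1}
#' e^{-2k^2T^2}}. Both statistics are reported because the raw D is bounded
#' by 1 while the scaled T is not; published "D statistics" above 1 are the
#' scaled form.
#'
#' @param crude,adjusted numeric vectors (at least 2 points each).
#' @return list with \code{D}, \code{T}, \code{p_value}, \code{n1},
#'   \code{n2}.
#' @export
ks_compare <- function(crude, adjusted) {
  x <- crude[is.finite(crude)]
  y <- adjusted[is.finite(adjusted)]
  if (length(x) < 2L || length(y) < 2L)
    stop_mgmt("ks_compare needs at least 2 points per sample",
              class = "mgmtperf_data_error")
  pooled <- sort(unique(c(x, y)))
  F1 <- vapply(pooled, function(t) mean(x <= t), numeric(1))
  F2 <- vapply(pooled, function(t) mean(y <= t), numeric(1))
  D <- max(abs(F1 - F2))
  n1 <- length(x); n2 <- length(y)
  T_stat <- sqrt(n1 * n2 / (n1 + n2)) * D
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * T_stat^2))
  list(D = D, T = T_stat, p_value = min(max(p, 0), 1), n1 = n1, n2 = n2)
}
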