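#' Z-score practice items
#'
#' Normalizes each item column by demeaning and dividing by its sample
#' standard deviation (n - 1 denominator). Items with zero variance across
#' CBOs carry no ranking information and cannot be standardized; they are
#' dropped and reported, never imputed.
#'
#' @param matrix an \code{mgmt_practice_matrix}, or a plain numeric matrix
#'   with column names (the normalization itself does not require binary
#'   values).
#' @return a list with \code{z} (the normalized matrix restricted to kept
#'   items), \code{kept} and \code{dropped} (item name vectors), and
#'   \code{domain_map} when the input carried one.
#' @export
zscore_items <- function(matrix) {
  domain_map <- NULL
  if (inherits(matrix, "mgmt_practice_matrix")) {
    domain_map <- matrix$domain_map
    matrix <- matrix$items
  }
  m <- as.matrix(matrix)
  if (nrow(m) < 3L)
    stop_mgmt("need at least 3 CBOs to standardize items (got %d)", nrow(m),
              class = "mgmtperf_data_error")
  mu <- colMeans(m)
  s <- apply(m, 2L, sd)
  keep <- s > 0
  z <- sweep(sweep(m[, keep, drop = FALSE], 2L, mu[keep], "-"),
             2L, s[keep], "/")
  list(z = z,
       kept = colnames(m)[keep],
       dropped = colnames(m)[!keep],
       domain_map = if (!is.null(domain_map)) domain_map[keep])
}

#' Inverse-covariance (GLS) weights for one domain block
#'
#' Computes the efficient summary-index weights for a block of standardized
#' items: with \eqn{\Sigma} the sample covariance of the z-scored items, the
#' index is \eqn{(1'\Sigma^{-1}1)^{-1} 1'\Sigma^{-1} \tilde{x}}, i.e. weights
#' proportional to the row sums of \eqn{\Sigma^{-1}}, normalized to sum
#' to 1. Redundant (highly correlated) items share weight; items carrying
#' independent signal are up-weighted. When \eqn{\Sigma} is ill-conditioned
#' (more items than CBOs, or near-duplicate items) a ridge term
#' \eqn{\lambda I} is added before inversion, with \eqn{\lambda} starting at
#' \code{ridge_init} times the mean diagonal and escalating tenfold until
#' the condition number drops below \code{cond_threshold}; any
#' regularization is recorded in the result.
#'
#' @param z_block numeric matrix of z-scored items (one domain).
#' @param ridge one of \code{"auto"} (default), a non-negative number used
#'   as a fixed ridge, or \code{"none"} to forbid regularization.
#' @param cond_threshold maximum acceptable condition number (default 1e10).
#' @param ridge_init initial ridge as a fraction of the mean diagonal
#'   (default 1e-6).
#' @param domain optional domain label used in messages.
#' @return an object of class \code{mgmt_domain_weighting}: list with
#'   \code{kept_items}, \code{weights} (summing to 1),
#'   \code{covariance_condition}, \code{regularization_used},
#'   \code{ridge}.
#' @export
gls_weights <- function(z_block, ridge = "auto", cond_threshold = 1e10,
                        ridge_init = 1e-6, domain = "block") {
  z_block <- as.matrix(z_block)
  if (ncol(z_block) < 1L)
    stop_mgmt("domain '%s' has no scorable items", domain,
              class = "mgmtperf_domain_error")
  if (ncol(z_block) == 1L) {
    return(structure(list(kept_items = colnames(z_block), weights = 1,
                          covariance_condition = 1,
                          regularization_used = FALSE, ridge = 0),
                     class = "mgmt_domain_weighting"))
  }
  S <- cov(z_block)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  lambda <- 0
  used <- FALSE
  if (cond > cond_threshold) {
    if (identical(ridge, "none"))
      stop_mgmt(
        "covariance of domain '%s' is singular (condition %.3g) and ridge regularization is disabled",
        domain, cond, class = "mgmtperf_numeric_error")
    lambda <- if (is.numeric(ridge) && ridge > 0) ridge else
      ridge_init * mean(diag(S))
    while ((max(ev) + lambda) / (max(min(ev), 0) + lambda) > cond_threshold)
      lambda <- lambda * 10
    used <- TRUE
  } else if (is.numeric(ridge) && ridge > 0) {
    lambda <- ridge
    used <- TRUE
  }
  Sr <- S + diag(lambda, ncol(S))
  inv_rows <- rowSums(solve(Sr))
  w <- inv_rows / sum(inv_rows)
  structure(list(kept_items = colnames(z_block), weights = unname(w),
                 covariance_condition = cond,
                 regularization_used = used, ridge = lambda),
            class = "mgmt_domain_weighting")
}

# Score a numeric item matrix (no binary requirement): z-score, drop
# degenerate items, GLS-weight per domain, then one overall score.
score_matrix <- function(items, domain_map, overall_mode = c("domains",
                                                             "items"),
                         ridge = "auto", cond_threshold = 1e10) {
  overall_mode <- match.arg(overall_mode)
  zs <- zscore_items(if (inherits(items, "mgmt_practice_matrix")) items else
    structure(list(items = as.matrix(items), domain_map = domain_map,
                   cbo_ids = rownames(items)),
    class = "mgmt_practice_matrix"))
  domains <- intersect(DOMAIN_NAMES, unique(domain_map))
  weightings <- list()
  domain_scores <- matrix(NA_real_, nrow(zs$z), length(domains),
                          dimnames = list(rownames(zs$z), domains))
  for (d in domains) {
    cols <- zs$kept[zs$domain_map == d]
    if (length(cols) == 0L)
      stop_mgmt("domain '%s' is unscorable: all its items are degenerate", d,
                class = "mgmtperf_domain_error")
    w <- gls_weights(zs$z[, cols, drop = FALSE], ridge = ridge,
                     cond_threshold = cond_threshold, domain = d)
    weightings[[d]] <- w
    domain_scores[, d] <- drop(zs$z[, cols, drop = FALSE] %*% w$weights)
  }
  if (overall_mode == "items") {
    w_all <- gls_weights(zs$z, ridge = ridge,
                         cond_threshold = cond_threshold, domain = "overall")
    overall <- drop(zs$z %*% w_all$weights)
  } else {
    std_dom <- scale(domain_scores)
    w_all <- gls_weights(std_dom, ridge = ridge,
                         cond_threshold = cond_threshold, domain = "overall")
    overall <- drop(std_dom %*% w_all$weights)
  }
  weightings[["overall"]] <- w_all
  list(domain_scores = domain_scores, overall = overall,
       weightings = weightings, dropped = zs$dropped)
}

#' Compute the seven management scores
#'
#' Produces one score per management domain (six) plus one overall
#' management score per CBO. Each domain score is the GLS-weighted average
#' of its z-scored items (\code{\link{gls_weights}}); the overall score is
#' built, per \code{overall_mode}, either from the six (standardized)
#' domain scores (\code{"domains"}, the default) or from all items jointly
#' (\code{"items"}). The domains default exists because with 67 items and
#' typically ~45 CBOs the all-items covariance is singular and the
#' ridge-inverted weights degrade the score badly; the six-score covariance
#' is well conditioned. All seven scores are finally re-standardized to mean
#' 0, SD 1 across CBOs, so downstream regression coefficients read as the
#' change in an outcome per one standard deviation of management.
#'
#' @param matrix an \code{mgmt_practice_matrix}.
#' @param overall_mode \code{"items"} or \code{"domains"}.
#' @param ridge,cond_threshold passed to \code{\link{gls_weights}}.
#' @return an object of class \code{mgmt_scores}: list with \code{cbo_ids},
#'   \code{domain_scores} (CBO x 6), \code{overall_score},
#'   \code{weightings}, \code{dropped_items}, \code{overall_mode}.
#' @examples
#' b <- generate_cbo_panel(generator_config(seed = 1))
#' sc <- compute_scores(b$practice_matrix)
#' round(colMeans(sc$domain_scores), 12)   # all zero
#' @export
compute_scores <- function(matrix, overall_mode = c("domains", "items"),
                           ridge = "auto", cond_threshold = 1e10) {
  overall_mode <- match.arg(overall_mode)
  if (!inherits(matrix, "mgmt_practice_matrix"))
    stop_mgmt("compute_scores expects an mgmt_practice_matrix",
              class = "mgmtperf_data_error")
  res <- score_matrix(matrix, matrix$domain_map, overall_mode = overall_mode,
                      ridge = ridge, cond_threshold = cond_threshold)
  std <- function(x) as.numeric(scale(x))
  ds <- apply(res$domain_scores, 2L, std)
  rownames(ds) <- matrix$cbo_ids
  structure(list(cbo_ids = matrix$cbo_ids,
                 domain_scores = ds,
                 overall_score = std(res$overall),
                 weightings = res$weightings,
                 dropped_items = res$dropped,
                 overall_mode = overall_mode),
            class = "mgmt_scores")
}

#' @export
print.mgmt_scores <- function(x, ...) {
  cat(sprintf("<mgmt_scores> %d CBOs, 6 domain scores + overall (%s mode)\n",
              length(x$cbo_ids), x$overall_mode))
  if (length(x$dropped_items))
    cat("  dropped zero-variance items:",
        paste(x$dropped_items, collapse = ", "), "\n")
  reg <- vapply(x$weightings, function(w) w$regularization_used, logical(1))
  if (any(reg))
    cat("  ridge regularization used for:",
        paste(names(x$weightings)[reg], collapse = ", "), "\n")
  invisible(x)
}

#' Scores as a data frame
#'
#' @param x an \code{mgmt_scores} object.
#' @param row.names,optional,... standard \code{as.data.frame} arguments.
#' @return data frame with cbo_id, six domain score columns and overall.
#' @export
as.data.frame.mgmt_scores <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  out <- data.frame(cbo_id = x$cbo_ids, x$domain_scores,
                    overall = x$overall_score,
                    stringsAsFactors = FALSE, row.names = row.names)
  out
}
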