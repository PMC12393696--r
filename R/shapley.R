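# Centered R-squared of y on (intercept | X), rank-deficiency safe: a
# rank-deficient design contributes the R-squared of its column space.
subset_r2 <- function(y, X) {
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(NA_real_)
  if (is.null(X) || ncol(X) == 0L) return(0)
  qx <- qr(cbind(1, X))
  rss <- sum(qr.resid(qx, y)^2)
  1 - rss / tss
}

#' Shapley (Shorrocks) decomposition of explained variance
#'
#' Allocates the R-squared of a linear model across groups of regressors
#' ("players"). Player \eqn{j}'s contribution is its average marginal
#' R-squared gain over all \eqn{2^{p-1}} subsets of the other players:
#' \deqn{\phi_j = \sum_{S \not\ni j} \frac{|S|!\,(p-|S|-1)!}{p!}
#'   \left[R^2(S \cup \{j\}) - R^2(S)\right]}
#' where every subset model also includes the \code{fixed} block (and the
#' empty-subset baseline is the fixed block alone, or 0 without one). The
#' contributions are order-independent and sum exactly to the full model's
#' R-squared minus the baseline; with the baseline attributed to the fixed
#' block, all shares sum to the full R-squared. Negative marginal
#' contributions (suppression) are reported as-is.
#'
#' @param y outcome vector.
#' @param players named list of regressor blocks (vector or matrix each).
#' @param fixed optional always-included regressor block.
#' @return an object of class \code{mgmt_shapley_result}: \code{players},
#'   \code{absolute_contribution} (one entry per player, plus
#'   \code{"(fixed)"} when a fixed block is supplied),
#'   \code{relative_pct} (share of total R-squared, in percent),
#'   \code{total_r2}, \code{n_subsets_evaluated}, \code{n}.
#' @examples
#' set.seed(1)
#' x1 <- rnorm(40); x2 <- rnorm(40)
#' y <- x1 + 0.5 * x2 + rnorm(40)
#' shapley_r2(y, list(a = x1, b = x2))
#' @export
shapley_r2 <- function(y, players, fixed = NULL) {
  p <- length(players)
  if (p < 1L)
    stop_mgmt("shapley_r2 needs at least one player",
              class = "mgmtperf_data_error")
  if (p > 12L)
    stop_mgmt("shapley_r2 supports at most 12 players (got %d)", p,
              class = "mgmtperf_data_error")
  if (is.null(names(players)))
    names(players) <- paste0("player", seq_len(p))
  blocks <- lapply(players, function(b) as.matrix(b))
  fixed <- if (!is.null(fixed)) as.matrix(fixed)
  cc <- complete.cases(y, do.call(cbind, c(blocks, list(fixed))))
  y <- y[cc]
  blocks <- lapply(blocks, function(b) b[cc, , drop = FALSE])
  if (!is.null(fixed)) fixed <- fixed[cc, , drop = FALSE]
  if (length(y) <= p + 1L + NCOL(fixed %||% matrix(nrow = 0, ncol = 0)))
    stop_mgmt("too few complete rows (%d) for %d players", length(y), p,
              class = "mgmtperf_data_error")

  n_sub <- bitwShiftL(1L, p)
  r2 <- numeric(n_sub)
  for (s in 0:(n_sub - 1L)) {
    sel <- which(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    X <- do.call(cbind, c(list(fixed), blocks[sel]))
    r2[s + 1L] <- subset_r2(y, X)
  }
  wt <- factorial(0:(p - 1L)) * factorial(p - 1L - 0:(p - 1L)) / factorial(p)
  contrib <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (s in 0:(n_sub - 1L)) {
      if (bitwAnd(s, bit) != 0L) next
      size <- sum(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      contrib[j] <- contrib[j] + wt[size + 1L] * (r2[s + bit + 1L] -
                                                    r2[s + 1L])
    }
  }
  names(contrib) <- names(players)
  total <- r2[n_sub]
  abs_contrib <- contrib
  if (!is.null(fixed)) abs_contrib <- c(abs_contrib, "(fixed)" = r2[1L])
  rel <- 100 * abs_contrib / total
  structure(list(players = names(players),
                 absolute_contribution = abs_contrib,
                 relative_pct = rel, total_r2 = total,
                 n_subsets_evaluated = n_sub, n = length(y)),
            class = "mgmt_shapley_result")
}

#' @export
print.mgmt_shapley_result <- function(x, ...) {
  cat(sprintf("<mgmt_shapley_result> total R2 = %.4f over %d subsets\n",
              x$total_r2, x$n_subsets_evaluated))
  print(round(rbind(absolute = x$absolute_contribution,
                    `pct of R2` = x$relative_pct), 4))
  invisible(x)
}

#' Relative contribution of each management dimension per outcome
#'
#' Runs the Shapley R-squared decomposition of the six-dimension model for
#' every performance indicator and tabulates the relative contribution of
#' each management domain, in percent of the model's total R-squared. For
#' unit-cost outcomes the intervention scale control enters as a genuine
#' seventh player whose share is computed but (by default) suppressed from
#' the display, so unit-cost columns sum to less than 100 whenever the
#' scale share is positive; the other columns sum to 100 exactly.
#'
#' @param adjusted an \code{mgmt_adjusted_scores} object.
#' @param panel performance panel data frame.
#' @param use_scale include the scale player in unit-cost models.
#' @param show_fixed_player if TRUE, add a row for the scale player's share.
#' @param scale_treatment \code{"player"} (default: scale is a Shapley
#'   player) or \code{"fixed"} (scale partialled out as an always-included
#'   block).
#' @param outcomes outcome subset (default all seven).
#' @return list with \code{table} (domains x outcomes matrix of
#'   percentages), \code{results} (per-outcome
#'   \code{mgmt_shapley_result}).
#' @export
shapley_table <- function(adjusted, panel, use_scale = TRUE,
                          show_fixed_player = FALSE,
                          scale_treatment = c("player", "fixed"),
                          outcomes = OUTCOME_INFO$outcome) {
  scale_treatment <- match.arg(scale_treatment)
  idx <- join_scores_panel(adjusted, panel)
  doms <- colnames(adjusted$adjusted)
  doms <- doms[doms != "overall"]
  results <- list()
  for (o in outcomes) {
    if (!o %in% names(panel))
      stop_mgmt("outcome '%s' not present in panel", o,
                class = "mgmtperf_data_error")
    players <- lapply(doms, function(d) adjusted$adjusted[idx, d])
    names(players) <- doms
    fixed <- NULL
    info <- OUTCOME_INFO[OUTCOME_INFO$outcome == o, ]
    if (use_scale && nrow(info) && !is.na(info$scale)) {
      if (scale_treatment == "player")
        players$scale <- panel[[info$scale]]
      else fixed <- panel[[info$scale]]
    }
    results[[o]] <- shapley_r2(panel[[o]], players, fixed = fixed)
  }
  rows <- if (show_fixed_player) c(doms, "scale") else doms
  tab <- matrix(NA_real_, length(rows), length(outcomes),
                dimnames = list(rows, outcomes))
  for (o in outcomes) {
    rel <- results[[o]]$relative_pct
    for (r in rows) if (r %in% names(rel)) tab[r, o] <- rel[[r]]
  }
  list(table = tab, results = results)
}
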