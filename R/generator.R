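#' Configuration for the synthetic CBO panel generator
#'
#' Builds and validates the full parameter set of the synthetic-data
#' generator. Defaults describe a 45-CBO, two-fiscal-year panel (30 CBOs in
#' country A, 15 in country B) with 67 binary management-practice items in
#' six domains, context covariates correlated with a latent management
#' quality, and seven performance outcomes linked to that latent quality by
#' known coefficients. Marginal distributions are calibrated so that
#' simulated context variables and outcomes fall in the ranges observed for
#' real community-based HIV service organizations (years open averaging
#' about five, staff about seven, ART unit cost near $850, HIV-testing
#' volume near 1,900 per year, and so on).
#'
#' @param n_cbos number of CBOs (default 45).
#' @param country_split proportion of CBOs in country A (default 30/45).
#' @param n_years number of fiscal years in the panel (default 2).
#' @param domain_item_counts named integer vector of items per domain;
#'   defaults to the canonical 7/18/20/11/7/4 layout summing to 67.
#' @param latent_loading logit slope of each practice item on the latent
#'   management quality z (default 1.2).
#' @param context_effects named vector of coefficients tying context
#'   covariates to z (log/logit scale, see Details).
#' @param outcome_mean named vector of outcome intercepts (value at z = 0).
#' @param beta_true named vector of true management coefficients: the change
#'   in each outcome per 1 SD of latent quality.
#' @param noise_sd named vector of residual SDs per outcome.
#' @param quantile_scale named vector of location-scale (heteroskedasticity)
#'   coefficients: residual SD is \code{noise_sd * (1 + quantile_scale * z)}
#'   (clamped below at 0.05), so true quantile slopes are
#'   \code{beta_true + quantile_scale * noise_sd * qnorm(q)}. Default -0.2
#'   for the three unit costs (better-managed CBOs have less dispersed
#'   costs, so the management effect is strongest at the upper cost
#'   quantiles), 0 elsewhere.
#' @param missing_art_rows number of CBO-years whose ART outcomes (unit cost
#'   and persons on ART) are deleted at random (default 1, reproducing the
#'   89-vs-90 complete-case asymmetry).
#' @param cost_floor positive floor applied to simulated unit costs
#'   (default $1).
#' @param seed integer RNG seed.
#'
#' @details Latent quality z is standard normal per CBO and is the single
#' ground truth driving items, context and outcomes. Management is a
#' CBO-level trait: one draw of z (and hence one set of practice items) is
#' shared by both fiscal years, so the panel carries repeated management
#' values within CBOs. Items are Bernoulli with logit linear in z, with
#' item-specific intercepts spread over \code{[-1, 1]} so prevalences vary.
#'
#' @return an object of class \code{mgmt_generator_config}.
#' @export
generator_config <- function(n_cbos = 45L,
                             country_split = 30 / 45,
                             n_years = 2L,
                             domain_item_counts = DOMAIN_ITEM_COUNTS,
                             latent_loading = 1.2,
                             context_effects = c(manager_degree = 0.6,
                                                 years_open = 0.15,
                                                 staff_n = 0.12,
                                                 competitors_30min = 0.10),
                             outcome_mean = c(uc_art = 847, uc_hts = 68,
                                              uc_sti = 39, n_art = 112,
                                              n_hts = 1888, n_sti = 2273,
                                              condoms_per_reached = 275),
                             beta_true = c(uc_art = -200, uc_hts = -15,
                                           uc_sti = -8, n_art = 20,
                                           n_hts = 500, n_sti = 400,
                                           condoms_per_reached = 60),
                             noise_sd = c(uc_art = 250, uc_hts = 18,
                                          uc_sti = 10, n_art = 30,
                                          n_hts = 500, n_sti = 700,
                                          condoms_per_reached = 100),
                             quantile_scale = c(uc_art = -0.2, uc_hts = -0.2,
                                                uc_sti = -0.2, n_art = 0,
                                                n_hts = 0, n_sti = 0,
                                                condoms_per_reached = 0),
                             missing_art_rows = 1L,
                             cost_floor = 1,
                             seed = 1L) {
  n_cbos <- check_scalar_count(n_cbos, "n_cbos", min = 3L)
  n_years <- check_scalar_count(n_years, "n_years", min = 1L)
  if (!is.numeric(country_split) || length(country_split) != 1L ||
      is.na(country_split) || country_split <= 0 || country_split >= 1)
    stop_mgmt("field 'country_split' must lie strictly in (0, 1)",
              class = "mgmtperf_config_error")
  if (is.null(names(domain_item_counts)) ||
      !all(names(domain_item_counts) %in% DOMAIN_NAMES) ||
      any(duplicated(names(domain_item_counts))))
    stop_mgmt("field 'domain_item_counts' must be named by the six domains",
              class = "mgmtperf_config_error")
  if (any(domain_item_counts < 1) ||
      any(domain_item_counts != as.integer(domain_item_counts)))
    stop_mgmt("field 'domain_item_counts' must hold positive integers",
              class = "mgmtperf_config_error")
  outcomes <- OUTCOME_INFO$outcome
  for (nm in c("outcome_mean", "beta_true", "noise_sd", "quantile_scale")) {
    v <- get(nm)
    if (!all(outcomes %in% names(v)))
      stop_mgmt("field '%s' must name all seven outcomes", nm,
                class = "mgmtperf_config_error")
  }
  if (any(noise_sd[outcomes] <= 0))
    stop_mgmt("field 'noise_sd' must be strictly positive",
              class = "mgmtperf_config_error")
  missing_art_rows <- check_scalar_count(missing_art_rows,
                                         "missing_art_rows", min = 0L)
  if (missing_art_rows >= n_cbos * n_years)
    stop_mgmt("field 'missing_art_rows' must leave at least one ART row",
              class = "mgmtperf_config_error")
  if (cost_floor <= 0)
    stop_mgmt("field 'cost_floor' must be strictly positive",
              class = "mgmtperf_config_error")
  structure(list(
    n_cbos = n_cbos, country_split = country_split, n_years = n_years,
    domain_item_counts = {
      ord <- intersect(DOMAIN_NAMES, names(domain_item_counts))
      stats::setNames(as.integer(domain_item_counts[ord]), ord)
    },
    latent_loading = latent_loading,
    context_effects = context_effects,
    outcome_mean = outcome_mean[outcomes],
    beta_true = beta_true[outcomes],
    noise_sd = noise_sd[outcomes],
    quantile_scale = quantile_scale[outcomes],
    missing_art_rows = missing_art_rows,
    cost_floor = cost_floor,
    seed = as.integer(seed)
  ), class = "mgmt_generator_config")
}

#' Generate a synthetic CBO panel with known ground truth
#'
#' Draws a complete synthetic bundle: a binary practice matrix, a CBO-level
#' context table, and a CBO-by-fiscal-year performance panel, together with
#' the latent truth that generated them. Outcomes are linear in the latent
#' management quality z with configurable residual SD; unit costs use a
#' location-scale construction (residual SD linear in z) so that true
#' conditional-quantile slopes differ across quantiles and are available in
#' closed form.
#'
#' @param config a \code{\link{generator_config}} object.
#' @return an object of class \code{mgmt_bundle}: a list with elements
#'   \code{practice_matrix}, \code{context_table}, \code{performance_panel},
#'   \code{truth} and \code{config}.
#' @examples
#' b <- generate_cbo_panel(generator_config(seed = 7))
#' nrow(b$context_table)            # 45 CBOs
#' table(b$context_table$country)   # 30 in country A, 15 in country B
#' sum(!is.na(b$performance_panel$uc_art))  # 89 complete ART rows
#' @export
generate_cbo_panel <- function(config = generator_config()) {
  if (!inherits(config, "mgmt_generator_config"))
    config <- do.call(generator_config, as.list(config))
  set.seed(config$seed)
  n <- config$n_cbos
  cbo_ids <- sprintf("CBO_%02d", seq_len(n))

  # Latent management quality: the single ground truth.
  z <- rnorm(n)

  # Context covariates, correlated with z through the configured effects.
  ce <- function(nm) unname(config$context_effects[nm] %||% 0)
  n_a <- round(n * config$country_split)
  country <- c(rep(0L, n_a), rep(1L, n - n_a))  # 1 = country B
  manager_degree <- rbinom(n, 1L, plogis(qlogis(0.53) +
                                           ce("manager_degree") * z))
  years_open <- pmin(pmax(round(exp(rnorm(n, log(4), 0.6) +
                                      ce("years_open") * z)), 1L), 16L)
  staff_n <- pmin(pmax(round(exp(rnorm(n, log(6), 0.45) +
                                   ce("staff_n") * z)), 2L), 21L)
  competitors <- pmin(rpois(n, exp(log(2) + ce("competitors_30min") * z)), 5L)
  context <- data.frame(cbo_id = cbo_ids, country = country,
                        manager_degree = manager_degree,
                        years_open = years_open, staff_n = staff_n,
                        competitors_30min = competitors,
                        stringsAsFactors = FALSE)

  # Binary practice items: Bernoulli with logit linear in z. Item-specific
  # intercepts are spread over [-1, 1] within each domain.
  counts <- config$domain_item_counts
  domain_map <- rep(names(counts), counts)
  item_names <- unlist(lapply(names(counts), function(d) {
    sprintf("%s_item%02d", d, seq_len(counts[[d]]))
  }), use.names = FALSE)
  alphas <- unlist(lapply(counts, function(J) {
    if (J == 1L) 0 else seq(-1, 1, length.out = J)
  }), use.names = FALSE)
  items <- matrix(0L, n, length(item_names),
                  dimnames = list(cbo_ids, item_names))
  for (j in seq_along(item_names)) {
    items[, j] <- rbinom(n, 1L, plogis(alphas[j] + config$latent_loading * z))
  }
  pm <- practice_matrix(items, stats::setNames(domain_map, item_names),
                        cbo_ids)

  # Performance panel: management (z) is a CBO trait shared by both years;
  # outcome noise is redrawn per CBO-year.
  years <- 2018L + seq_len(config$n_years) - 1L
  panel <- data.frame(cbo_id = rep(cbo_ids, times = config$n_years),
                      fiscal_year = rep(years, each = n),
                      stringsAsFactors = FALSE)
  zz <- rep(z, times = config$n_years)
  nr <- nrow(panel)
  for (o in OUTCOME_INFO$outcome) {
    mu <- config$outcome_mean[[o]] + config$beta_true[[o]] * zz
    sdv <- config$noise_sd[[o]] * pmax(1 + config$quantile_scale[[o]] * zz,
                                       0.05)
    y <- rnorm(nr, mu, sdv)
    blk <- OUTCOME_INFO$block[OUTCOME_INFO$outcome == o]
    panel[[o]] <- switch(blk,
      unit_cost = pmax(y, config$cost_floor),
      volume = as.integer(pmax(round(y), 0)),
      outreach_quality = pmax(y, config$cost_floor))
  }
  panel$scale_art <- panel$n_art
  panel$scale_hts <- panel$n_hts
  panel$scale_sti <- panel$n_sti

  # Delete ART outcomes in a few random CBO-years (N = 89 vs 90 asymmetry).
  if (config$missing_art_rows > 0L) {
    drop <- sample.int(nr, config$missing_art_rows)
    panel$uc_art[drop] <- NA_real_
    panel$n_art[drop] <- NA_integer_
    panel$scale_art[drop] <- NA_integer_
  }

  qs <- c(0.25, 0.50, 0.75, 0.95)
  true_gamma2 <- sapply(OUTCOME_INFO$outcome, function(o) {
    config$beta_true[[o]] +
      config$quantile_scale[[o]] * config$noise_sd[[o]] * qnorm(qs)
  })
  rownames(true_gamma2) <- sprintf("q%02d", qs * 100)

  structure(list(
    practice_matrix = pm,
    context_table = context,
    performance_panel = panel,
    truth = list(cbo_id = cbo_ids, z = z,
                 beta_true = config$beta_true,
                 outcome_mean = config$outcome_mean,
                 noise_sd = config$noise_sd,
                 quantile_scale = config$quantile_scale,
                 true_quantile_slopes = true_gamma2,
                 seed = config$seed),
    config = config
  ), class = "mgmt_bundle")
}

#' @export
print.mgmt_bundle <- function(x, ...) {
  cat(sprintf("<mgmt_bundle> %d CBOs x %d years, %d practice items\n",
              x$config$n_cbos, x$config$n_years,
              ncol(x$practice_matrix$items)))
  cat(sprintf("  panel rows: %d (complete ART rows: %d)\n",
              nrow(x$performance_panel),
              sum(!is.na(x$performance_panel$uc_art))))
  invisible(x)
}
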