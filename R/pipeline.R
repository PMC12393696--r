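#' Configuration of a full pipeline run
#'
#' Collects everything one end-to-end run needs: either a generator
#' configuration (simulate) or a directory of input CSVs, plus the
#' analysis options of every stage. Each stochastic stage draws its seed
#' deterministically from the single global seed.
#'
#' @param generator a \code{\link{generator_config}}, or NULL to read
#'   inputs from \code{input_dir}.
#' @param input_dir directory with practices/context/performance CSVs
#'   (ignored when \code{generator} is supplied).
#' @param out_dir output directory, or NULL to skip writing files.
#' @param adjustment_mode \code{"residual"} (the default; see
#'   \code{\link{adjust_scores}} for why) or \code{"fitted"}.
#' @param restandardize re-scale adjusted scores to mean 0, SD 1.
#' @param hc_type robust-covariance flavour for OLS stages.
#' @param overall_mode overall-score construction, \code{"items"} or
#'   \code{"domains"}.
#' @param quantiles quantile levels for the quantile stage.
#' @param B bootstrap replicates for cross-quantile tests.
#' @param seed global integer seed.
#' @param make_figure write an SVG comparing crude and adjusted score
#'   densities (requires \code{out_dir}).
#' @return a \code{mgmt_run_config} list.
#' @export
run_config <- function(generator = generator_config(), input_dir = NULL,
                       out_dir = NULL,
                       adjustment_mode = c("residual", "fitted"),
                       restandardize = FALSE, hc_type = "HC1",
                       overall_mode = c("domains", "items"),
                       quantiles = c(0.25, 0.50, 0.75, 0.95),
                       B = 500L, seed = 1L, make_figure = !is.null(out_dir)) {
  structure(list(generator = generator, input_dir = input_dir,
                 out_dir = out_dir,
                 adjustment_mode = match.arg(adjustment_mode),
                 restandardize = restandardize, hc_type = hc_type,
                 overall_mode = match.arg(overall_mode),
                 quantiles = quantiles, B = as.integer(B),
                 seed = as.integer(seed), make_figure = make_figure),
            class = "mgmt_run_config")
}

#' Summary statistics in the style of a descriptive table
#'
#' Reports N, mean, median, minimum and maximum for the contextual
#' covariates (one row per CBO) and for every panel outcome (one row per
#' CBO-year), plus the total number of HIV services provided per CBO-year
#' (the sum of the three intervention volumes).
#'
#' @param bundle an \code{mgmt_bundle}.
#' @return data frame with columns variable, level, N, mean, median, min,
#'   max.
#' @export
descriptives <- function(bundle) {
  row1 <- function(name, level, x) {
    x <- x[!is.na(x)]
    data.frame(variable = name, level = level, N = length(x),
               mean = mean(x), median = median(x), min = min(x),
               max = max(x), stringsAsFactors = FALSE)
  }
  ctx <- bundle$context_table
  panel <- bundle$performance_panel
  total_services <- rowSums(panel[c("n_art", "n_hts", "n_sti")], na.rm = TRUE)
  out <- rbind(
    row1("prop_country_b", "CBO", ctx$country),
    row1("prop_manager_degree", "CBO", ctx$manager_degree),
    row1("years_open", "CBO", ctx$years_open),
    row1("staff_n", "CBO", ctx$staff_n),
    row1("competitors_30min", "CBO", ctx$competitors_30min),
    row1("total_services", "CBO-year", total_services),
    do.call(rbind, lapply(OUTCOME_INFO$outcome, function(o)
      row1(o, "CBO-year", panel[[o]])))
  )
  rownames(out) <- NULL
  out
}

write_density_figure <- function(crude, adjusted, path) {
  ok <- tryCatch({
    grDevices::svg(path, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    dc <- stats::density(crude); da <- stats::density(adjusted)
    plot(dc, main = "Crude vs adjusted overall management score",
         xlab = "z-score", ylim = range(dc$y, da$y), lwd = 2)
    graphics::lines(da, lwd = 2, lty = 2)
    graphics::legend("topright", c("crude", "adjusted"), lwd = 2,
                     lty = c(1, 2), bty = "n")
    TRUE
  }, error = function(e) FALSE)
  invisible(ok)
}

#' Run the full analysis pipeline
#'
#' Composes all stages: simulate (or read) the CBO bundle, build the seven
#' GLS management scores, adjust them for context, compare crude and
#' adjusted distributions (KS test), fit the per-outcome robust OLS models,
#' decompose explained variance across domains by Shapley values, and fit
#' the quantile models with bootstrap cross-quantile tests. All stage
#' outputs, a descriptive table, and a provenance block (seeds, dropped
#' items, regularization and listwise-deletion events) are returned and,
#' when \code{out_dir} is set, written as plain CSV/JSON files.
#'
#' @param config a \code{\link{run_config}}.
#' @return a \code{mgmt_run_report} list with elements \code{bundle},
#'   \code{scores}, \code{adjusted}, \code{ks}, \code{descriptives},
#'   \code{ols_fits}, \code{table2}, \code{shapley}, \code{quantile},
#'   \code{provenance}.
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mgmt("pipeline stage '%s' failed: %s", name, conditionMessage(e),
                class = "mgmtperf_pipeline_error")
    })
  }
  bundle <- stage("data", {
    if (!is.null(config$generator)) {
      gc <- config$generator
      gc$seed <- derive_seed(config$seed, 1L)
      generate_cbo_panel(gc)
    } else if (!is.null(config$input_dir)) {
      read_bundle(config$input_dir)
    } else stop("neither generator nor input_dir supplied")
  })
  scores <- stage("score", compute_scores(bundle$practice_matrix,
                                          overall_mode = config$overall_mode))
  adjusted <- stage("adjust", adjust_scores(scores, bundle$context_table,
                                            mode = config$adjustment_mode,
                                            restandardize =
                                              config$restandardize,
                                            hc_type = config$hc_type))
  ks <- stage("ks", ks_compare(scores$overall_score,
                               adjusted$adjusted[, "overall"]))
  desc <- stage("descriptives", descriptives(bundle))
  fits <- stage("regress",
                fit_performance_models(adjusted, bundle$performance_panel,
                                       hc_type = config$hc_type))
  tab2 <- regression_table(fits)
  shap <- stage("shapley", shapley_table(adjusted,
                                         bundle$performance_panel))
  quant <- stage("quantile",
                 quantile_table(adjusted, bundle$performance_panel,
                                quantiles = config$quantiles, B = config$B,
                                seed = derive_seed(config$seed, 2L)))
  ridge_events <- lapply(scores$weightings, function(w)
    if (w$regularization_used) w$ridge else NULL)
  provenance <- list(
    seed = config$seed,
    stage_seeds = list(data = derive_seed(config$seed, 1L),
                       quantile = derive_seed(config$seed, 2L)),
    adjustment_mode = config$adjustment_mode,
    overall_mode = config$overall_mode,
    hc_type = config$hc_type,
    B = config$B,
    dropped_items = scores$dropped_items,
    ridge_events = ridge_events[!vapply(ridge_events, is.null, logical(1))],
    model_n = vapply(fits, function(f) f$n, integer(1)),
    model_n_dropped = vapply(fits, function(f) f$n_dropped, integer(1)),
    package_version = as.character(utils::packageVersion("mgmtperf")))
  report <- structure(list(bundle = bundle, scores = scores,
                           adjusted = adjusted, ks = ks,
                           descriptives = desc, ols_fits = fits,
                           table2 = tab2, shapley = shap, quantile = quant,
                           provenance = provenance),
                      class = "mgmt_run_report")
  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    write_bundle(bundle, file.path(d, "data"))
    write.csv(as.data.frame(scores), file.path(d, "scores.csv"),
              row.names = FALSE)
    adj_df <- data.frame(cbo_id = adjusted$cbo_ids, adjusted$adjusted,
                         stringsAsFactors = FALSE)
    write.csv(adj_df, file.path(d, "adjusted.csv"), row.names = FALSE)
    write.csv(desc, file.path(d, "table1.csv"), row.names = FALSE)
    write.csv(tab2, file.path(d, "table2.csv"), row.names = FALSE)
    shap_df <- data.frame(domain = rownames(shap$table), shap$table,
                          check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(shap_df, file.path(d, "table3.csv"), row.names = FALSE)
    write.csv(quant$table, file.path(d, "table4.csv"), row.names = FALSE)
    jsonlite::write_json(ks, file.path(d, "ks.json"), auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(provenance, file.path(d, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (isTRUE(config$make_figure))
      write_density_figure(scores$overall_score,
                           adjusted$adjusted[, "overall"],
                           file.path(d, "fig1_crude_vs_adjusted.svg"))
  }
  report
}

#' @export
print.mgmt_run_report <- function(x, ...) {
  cat("<mgmt_run_report>\n")
  cat(sprintf("  %d CBOs, %d panel rows; KS D = %.3f (T = %.2f, p = %.3g)\n",
              length(x$scores$cbo_ids), nrow(x$bundle$performance_panel),
              x$ks$D, x$ks$T, x$ks$p_value))
  cat("  management coefficients (robust OLS):\n")
  for (o in names(x$ols_fits)) {
    f <- x$ols_fits[[o]]
    cat(sprintf("    %-20s %10.2f (SE %8.2f, n = %d)\n", o,
                f$coefficients[["management"]], f$se[["management"]], f$n))
  }
  invisible(x)
}
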