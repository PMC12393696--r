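#' Write a synthetic bundle to a directory of plain-text files
#'
#' Writes \code{practices.csv}, \code{context.csv}, \code{performance.csv}
#' and a \code{truth.json} sidecar holding the generator's ground truth.
#' The files round-trip: \code{read_bundle(write_bundle(b, d))} reproduces
#' the bundle field for field.
#'
#' @param bundle an \code{mgmt_bundle}.
#' @param directory output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  pm <- bundle$practice_matrix
  practices <- data.frame(cbo_id = pm$cbo_ids, pm$items,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(practices, file.path(directory, "practices.csv"),
            row.names = FALSE)
  write.csv(bundle$context_table, file.path(directory, "context.csv"),
            row.names = FALSE)
  write.csv(bundle$performance_panel, file.path(directory, "performance.csv"),
            row.names = FALSE)
  truth <- bundle$truth
  truth$true_quantile_slopes <- as.data.frame(truth$true_quantile_slopes)
  # named vectors must serialize as JSON objects, not bare arrays
  for (nm in c("beta_true", "outcome_mean", "noise_sd", "quantile_scale"))
    truth[[nm]] <- as.list(truth[[nm]])
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Read a synthetic bundle back from a directory
#'
#' Parses and validates the three CSV tables written by
#' \code{\link{write_bundle}} plus the \code{truth.json} sidecar (if
#' present). Validation covers the CSV headers, binary coding of the
#' practice items, duplicate CBO identifiers, and referential integrity of
#' the panel's CBO keys; violations raise parse errors naming the offending
#' row and column.
#'
#' @param directory directory holding the bundle files.
#' @return an \code{mgmt_bundle} (with \code{config = NULL} when the bundle
#'   was not produced by this package's generator).
#' @export
read_bundle <- function(directory) {
  fp <- function(f) file.path(directory, f)
  for (f in c("practices.csv", "context.csv", "performance.csv"))
    if (!file.exists(fp(f)))
      stop_mgmt("missing bundle file '%s' in %s", f, directory,
                class = "mgmtperf_parse_error")

  practices <- read.csv(fp("practices.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(practices)[1] != "cbo_id")
    stop_mgmt("practices.csv: first column must be 'cbo_id', found '%s'",
              names(practices)[1], class = "mgmtperf_parse_error")
  item_cols <- setdiff(names(practices), "cbo_id")
  # Item columns are named <domain>_itemNN; recover the domain map.
  dom <- sub("_item[0-9]+$", "", item_cols)
  bad_dom <- setdiff(unique(dom), DOMAIN_NAMES)
  if (length(bad_dom))
    stop_mgmt("practices.csv: malformed item columns (unknown domain): %s",
              paste(utils::head(item_cols[dom %in% bad_dom], 3),
                    collapse = ", "), class = "mgmtperf_parse_error")
  items <- as.matrix(practices[item_cols])
  pm <- practice_matrix(items, stats::setNames(dom, item_cols),
                        practices$cbo_id)

  context <- read.csv(fp("context.csv"), stringsAsFactors = FALSE)
  need <- c("cbo_id", CONTEXT_COVARIATES)
  miss <- setdiff(need, names(context))
  if (length(miss))
    stop_mgmt("context.csv: missing columns: %s",
              paste(miss, collapse = ", "), class = "mgmtperf_parse_error")
  if (anyDuplicated(context$cbo_id))
    stop_mgmt("context.csv: duplicate cbo_id '%s'",
              context$cbo_id[duplicated(context$cbo_id)][1],
              class = "mgmtperf_parse_error")

  panel <- read.csv(fp("performance.csv"), stringsAsFactors = FALSE)
  need <- c("cbo_id", "fiscal_year", OUTCOME_INFO$outcome,
            stats::na.omit(OUTCOME_INFO$scale))
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop_mgmt("performance.csv: missing columns: %s",
              paste(miss, collapse = ", "), class = "mgmtperf_parse_error")
  orphan <- setdiff(panel$cbo_id, pm$cbo_ids)
  if (length(orphan))
    stop_mgmt(
      "performance.csv: row %d references unknown cbo_id '%s'",
      which(panel$cbo_id %in% orphan)[1], orphan[1],
      class = "mgmtperf_integrity_error")
  uc <- as.matrix(panel[c("uc_art", "uc_hts", "uc_sti")])
  if (any(uc <= 0, na.rm = TRUE))
    stop_mgmt("performance.csv: non-positive unit cost at row %d",
              which(apply(uc <= 0, 1, any))[1],
              class = "mgmtperf_parse_error")

  truth <- NULL
  if (file.exists(fp("truth.json"))) {
    truth <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
    if (!is.null(truth$true_quantile_slopes))
      truth$true_quantile_slopes <- as.matrix(truth$true_quantile_slopes)
    for (nm in c("beta_true", "outcome_mean", "noise_sd", "quantile_scale"))
      if (!is.null(truth[[nm]])) truth[[nm]] <- unlist(truth[[nm]])
  }
  structure(list(practice_matrix = pm, context_table = context,
                 performance_panel = panel, truth = truth, config = NULL),
            class = "mgmt_bundle")
}
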