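#' Construct a validated practice matrix
#'
#' A practice matrix holds one row per CBO and one binary column per
#' management-practice item (1 = practice present, 0 = absent), together
#' with a map assigning every item to exactly one of the six management
#' domains: target setting, performance monitoring, people management,
#' operations management, financial management, community engagement.
#'
#' @param items numeric matrix of 0/1 values, CBOs in rows, items in
#'   columns; column names are item identifiers.
#' @param domain_map named character vector: item name -> domain name.
#' @param cbo_ids character vector of unique CBO identifiers (defaults to
#'   the matrix rownames).
#' @return an object of class \code{mgmt_practice_matrix}.
#' @export
practice_matrix <- function(items, domain_map, cbo_ids = rownames(items)) {
  items <- as.matrix(items)
  if (is.null(colnames(items)))
    stop_mgmt("practice matrix must have item column names",
              class = "mgmtperf_parse_error")
  if (is.null(cbo_ids)) cbo_ids <- sprintf("CBO_%02d", seq_len(nrow(items)))
  cbo_ids <- as.character(cbo_ids)
  if (anyDuplicated(cbo_ids))
    stop_mgmt("duplicate CBO identifiers: %s",
              paste(unique(cbo_ids[duplicated(cbo_ids)]), collapse = ", "),
              class = "mgmtperf_parse_error")
  if (length(cbo_ids) != nrow(items))
    stop_mgmt("cbo_ids length (%d) does not match matrix rows (%d)",
              length(cbo_ids), nrow(items), class = "mgmtperf_parse_error")
  bad <- which(!(items %in% c(0, 1)) | is.na(items))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(items))
    stop_mgmt(
      "non-binary item value %s at row %d (%s), column %d (%s)",
      format(items[bad[1L]]), rc[1], cbo_ids[rc[1]], rc[2],
      colnames(items)[rc[2]], class = "mgmtperf_parse_error")
  }
  missing_map <- setdiff(colnames(items), names(domain_map))
  if (length(missing_map))
    stop_mgmt("items missing from domain map: %s",
              paste(missing_map, collapse = ", "),
              class = "mgmtperf_parse_error")
  domain_map <- domain_map[colnames(items)]
  unknown <- setdiff(unique(domain_map), DOMAIN_NAMES)
  if (length(unknown))
    stop_mgmt("unknown domains in map: %s", paste(unknown, collapse = ", "),
              class = "mgmtperf_parse_error")
  rownames(items) <- cbo_ids
  structure(list(cbo_ids = cbo_ids,
                 items = matrix(as.numeric(items), nrow(items), ncol(items),
                                dimnames = dimnames(items)),
                 domain_map = domain_map),
            class = "mgmt_practice_matrix")
}

#' @export
print.mgmt_practice_matrix <- function(x, ...) {
  tab <- table(factor(x$domain_map, levels = DOMAIN_NAMES))
  cat(sprintf("<mgmt_practice_matrix> %d CBOs x %d items\n",
              length(x$cbo_ids), ncol(x$items)))
  for (d in names(tab)) cat(sprintf("  %-24s %d items\n", d, tab[[d]]))
  invisible(x)
}
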