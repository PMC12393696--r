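#' @useDynLib mgmtperf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef complete.cases cor cov lm.fit median pf pnorm pt
#'   qlogis qnorm quantile rbinom rlnorm rnorm rpois runif sd var dnorm plogis
#' @importFrom utils read.csv write.csv
NULL

# Canonical domain layout: six management domains and their item counts.
DOMAIN_NAMES <- c("target_setting", "performance_monitoring",
                  "people_management", "operations_management",
                  "financial_management", "community_engagement")

DOMAIN_ITEM_COUNTS <- c(target_setting = 7L, performance_monitoring = 18L,
                        people_management = 20L, operations_management = 11L,
                        financial_management = 7L, community_engagement = 4L)

# The seven outcome columns of the performance panel, their matching scale
# columns (unit-cost models only) and the outcome block each belongs to.
OUTCOME_INFO <- data.frame(
  outcome = c("uc_art", "uc_hts", "uc_sti",
              "n_art", "n_hts", "n_sti", "condoms_per_reached"),
  block   = c("unit_cost", "unit_cost", "unit_cost",
              "volume", "volume", "volume", "outreach_quality"),
  scale   = c("scale_art", "scale_hts", "scale_sti", NA, NA, NA, NA),
  stringsAsFactors = FALSE
)

CONTEXT_COVARIATES <- c("country", "manager_degree", "years_open",
                        "staff_n", "competitors_30min")

stop_mgmt <- function(fmt, ..., class) {
  stop(structure(class = c(class, "mgmtperf_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop_mgmt("field '%s' must be a single integer >= %d", name, min,
              class = "mgmtperf_config_error")
  as.integer(x)
}

# Deterministic child seeds from one master seed, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483629L
}
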