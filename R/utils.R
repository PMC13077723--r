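# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimals. Used for
#' all displayed percentages so that, e.g., 73.096 prints as 73.10; base
#' [round()] rounds half to even and would disagree on boundary cells.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalize a drug name for synonym matching
#'
#' Uppercases, trims, and collapses internal whitespace. Matching against a
#' synonym list is exact on the normalized form; no fuzzy matching is done.
#'
#' @param x character vector of drug names.
#' @return normalized character vector.
#' @export
normalize_drugname <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# yyyymmdd integer (or string) <-> Date. Unparseable values become NA.
yyyymmdd_to_date <- function(x) {
  x <- suppressWarnings(as.integer(x))
  as.Date(sprintf("%08d", x), format = "%Y%m%d", optional = TRUE)
}

date_to_yyyymmdd <- function(d) as.integer(format(d, "%Y%m%d"))

# sample from a named categorical marginal; returns character vector
sample_categorical <- function(n, marginal) {
  sample(names(marginal), n, replace = TRUE, prob = as.numeric(marginal))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("faersignal_config_error", "error")))
}

stop_ingest <- function(...) {
  stop(errorCondition(paste0(...), class = c("faersignal_ingest_error", "error")))
}
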