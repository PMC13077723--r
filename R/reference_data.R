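# Reference demographic profile for ketorolac (Toradol) reports.

#' Reference demographic counts for ketorolac reports
#'
#' Published demographic summary counts for FAERS reports (2004 Q1 to
#' 2017 Q4) in which ketorolac (Toradol) was the primary suspect drug:
#' category counts by reporting year, sex, age band, weight band, reporter
#' occupation, reporting country, administration route, outcome and
#' time-to-onset band. These counts calibrate the generator defaults and
#' let the count-(percent) machinery be checked against known percentages.
#'
#' @return data frame with columns `variable`, `category`, `count`.
#' @export
reference_demographics <- function() {
  path <- system.file("extdata", "toradol_demographic_counts.csv",
                      package = "faersignal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "integer"))
}

#' Recompute count-(percent) tables from the reference counts
#'
#' Applies [summary_from_counts()] to each variable of
#' [reference_demographics()], i.e. percent = 100 count / (sum of the
#' displayed category counts), rounded half-up to 2 decimals.
#'
#' @return named list of `summary_table` data frames.
#' @export
reference_summary_tables <- function() {
  ref <- reference_demographics()
  out <- lapply(split(ref, factor(ref$variable, levels = unique(ref$variable))),
                function(d) summary_from_counts(stats::setNames(d$count, d$category),
                                                variable = d$variable[1]))
  out
}
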