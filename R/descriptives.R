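# Descriptive summary machinery: categorical count-(percent) tables over an
# explicit denominator, banded age / weight / time-to-onset variables, and
# median (Q1, Q3) rows.

#' Band an age in years
#'
#' Half-open bands `[0,18) [18,45) [45,65) [65,75) [75,Inf)` labelled
#' `<18`, `18-45`, `45-65`, `65-75`, `>=75`; missing or negative ages band
#' as `Unknown` (negative with a warning).
#'
#' @param age_years numeric vector.
#' @return character vector of band labels.
#' @export
age_band <- function(age_years) {
  neg <- !is.na(age_years) & age_years < 0
  if (any(neg)) warning(sum(neg), " negative age(s) treated as Unknown")
  age_years[neg] <- NA
  out <- as.character(cut(as.numeric(age_years), c(0, 18, 45, 65, 75, Inf),
                          labels = c("<18", "18-45", "45-65", "65-75", ">=75"),
                          right = FALSE, include.lowest = FALSE))
  out[is.na(out)] <- "Unknown"
  out
}

#' Band a body weight in kilograms
#'
#' Half-open bands labelled `<60`, `60-80`, `>=80`; missing as `Unknown`.
#' @param wt_kg numeric vector.
#' @return character vector of band labels.
#' @export
weight_band <- function(wt_kg) {
  out <- as.character(cut(as.numeric(wt_kg), c(0, 60, 80, Inf),
                          labels = c("<60", "60-80", ">=80"), right = FALSE))
  out[is.na(out)] <- "Unknown"
  out
}

#' Band a time to onset in days
#'
#' Half-open bands `[0,7) [7,28) [28,60) [60,Inf)` labelled `<7`, `7-28`,
#' `28-60`, `>=60`; missing as `Unknown`.
#' @param tto_days numeric vector.
#' @return character vector of band labels.
#' @export
tto_band <- function(tto_days) {
  out <- as.character(cut(as.numeric(tto_days), c(0, 7, 28, 60, Inf),
                          labels = c("<7", "7-28", "28-60", ">=60"),
                          right = FALSE))
  out[is.na(out)] <- "Unknown"
  out
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics (type 7,
#' the R default); missing values are excluded. The `display` element is
#' rounded half-up to 2 decimals; the raw values are retained.
#'
#' @param values numeric vector with at least one non-missing value.
#' @return list with `median`, `q1`, `q3`, and `display` (rounded).
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                display = c(median = NA_real_, q1 = NA_real_, q3 = NA_real_)))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3],
       display = round_half_up(c(median = q[2], q1 = q[1], q3 = q[3]), 2))
}

#' Build a count-(percent) summary table from category values
#'
#' The denominator is the sum over the displayed categories only: cases
#' missing the variable are excluded unless an explicit `Unknown` category
#' is displayed. Percents are rounded half-up to 2 decimals.
#'
#' @param values character vector of category values (NA = missing).
#' @param variable variable name recorded in the table.
#' @param category_order optional fixed display order; categories absent
#'   from the data show a zero count.
#' @param include_unknown display missing values as an `Unknown` row.
#' @return a `summary_table` data frame with columns `variable`,
#'   `category`, `count`, `percent`, and attribute `denominator`.
#' @export
summary_table <- function(values, variable = "variable",
                          category_order = NULL, include_unknown = FALSE) {
  values <- as.character(values)
  if (include_unknown) values[is.na(values)] <- "Unknown"
  values <- values[!is.na(values)]
  counts <- table(values)
  if (is.null(category_order)) {
    category_order <- names(sort(counts, decreasing = TRUE))
    if (include_unknown && "Unknown" %in% category_order)
      category_order <- c(setdiff(category_order, "Unknown"), "Unknown")
  }
  cnt <- as.integer(counts[category_order])
  cnt[is.na(cnt)] <- 0L
  summary_from_counts(stats::setNames(cnt, category_order), variable)
}

#' Build a count-(percent) summary table from known counts
#'
#' The same layout as [summary_table()], computed directly from category
#' counts (e.g., counts transcribed from a published table): percent =
#' 100 count / denominator with the denominator equal to the sum of the
#' displayed counts, rounded half-up to 2 decimals.
#'
#' @param counts named integer vector of category counts.
#' @param variable variable name recorded in the table.
#' @return a `summary_table` data frame.
#' @export
summary_from_counts <- function(counts, variable = "variable") {
  denom <- sum(counts)
  pct <- if (denom > 0) round_half_up(100 * as.numeric(counts) / denom, 2) else
    rep(NA_real_, length(counts))
  out <- data.frame(variable = variable, category = names(counts),
                    count = as.integer(counts), percent = pct,
                    stringsAsFactors = FALSE)
  attr(out, "denominator") <- denom
  class(out) <- c("summary_table", "data.frame")
  out
}

summary_variables <- c("year", "sex", "age_band", "weight_band", "reporter",
                       "country", "route", "outcome", "tto_band")

# occp_cod / outc_cod display labels
occp_labels <- c(CN = "Consumer", MD = "Physician", OT = "Other health professional",
                 PH = "Pharmacist", LW = "Lawyer", RN = "Registered nurse")
outc_labels <- c(HO = "Hospitalization", OT = "Other serious",
                 LT = "Life threatening", DE = "Death", DS = "Disability",
                 RI = "Required intervention", CA = "Congenital anomaly")

case_variable_values <- function(cases, variable) {
  demo <- cases$demo
  switch(variable,
    year = as.character(demo$year),
    sex = as.character(demo$sex),
    age_band = age_band(demo$age_years),
    weight_band = weight_band(demo$wt),
    reporter = unname(occp_labels[as.character(demo$occp_cod)]),
    country = ifelse(is.na(demo$occr_country), NA_character_,
                     ifelse(demo$occr_country == "US", "United States", "Other")),
    route = {
      ps <- cases$drug[cases$drug$role_cod == "PS", , drop = FALSE]
      ps <- ps[!duplicated(ps$primaryid), , drop = FALSE]
      r <- ps$route[match(demo$primaryid, ps$primaryid)]
      ifelse(is.na(r), NA_character_,
             paste0(toupper(substring(r, 1, 1)), tolower(substring(r, 2))))
    },
    outcome = unname(outc_labels[as.character(cases$outc$outc_cod)]),
    tto_band = tto_band(demo$tto_days),
    stop_config("summarize_categorical: unknown variable '", variable, "'"))
}

#' Summarize one case variable as a count-(percent) table
#'
#' Supported variables: `year`, `sex`, `age_band`, `weight_band`,
#' `reporter`, `country`, `route`, `outcome`, `tto_band`. For `outcome`
#' the unit is the outcome record (a case may carry several); for all
#' others it is the case. By default an `Unknown` row is displayed for
#' `age_band`, `weight_band`, `reporter` and `tto_band`, and missing
#' values are excluded from the denominator elsewhere.
#'
#' @param cases a `faers_cases` object.
#' @param variable one of the supported variable names.
#' @param category_order optional fixed display order.
#' @param include_unknown display missing values as an `Unknown` row;
#'   default depends on the variable (see above).
#' @return a `summary_table` data frame.
#' @export
summarize_categorical <- function(cases, variable, category_order = NULL,
                                  include_unknown = NULL) {
  if (!variable %in% summary_variables)
    stop_config("summarize_categorical: unknown variable '", variable, "'")
  if (is.null(include_unknown))
    include_unknown <- variable %in% c("age_band", "weight_band", "reporter",
                                       "tto_band")
  values <- case_variable_values(cases, variable)
  if (is.null(category_order)) {
    category_order <- switch(variable,
      year = as.character(sort(unique(stats::na.omit(values)))),
      age_band = c("<18", "18-45", "45-65", "65-75", ">=75", "Unknown"),
      weight_band = c("<60", "60-80", ">=80", "Unknown"),
      tto_band = c("<7", "7-28", "28-60", ">=60", "Unknown"),
      NULL)
  }
  summary_table(values, variable = variable, category_order = category_order,
                include_unknown = include_unknown)
}

#' Full demographic summary of a case set
#'
#' One [summarize_categorical()] table per supported variable, plus median
#' (Q1, Q3) rows for age in years and time to onset in days.
#'
#' @param cases a `faers_cases` object.
#' @return named list: `tables` (list of `summary_table`s) and `medians`
#'   (list with `age_years`, `tto_days`).
#' @export
demographic_summary <- function(cases) {
  tables <- lapply(stats::setNames(nm = summary_variables),
                   function(v) summarize_categorical(cases, v))
  list(tables = tables,
       medians = list(age_years = median_iqr(cases$demo$age_years),
                      tto_days = median_iqr(cases$demo$tto_days)))
}
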