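# 2x2 contingency tables for (target drug, event) pairs.
#
# The unit of counting is the report (deduplicated case): for an event E,
#   a = cases where the target drug is primary suspect and E is present
#   b = primary-suspect target cases without E
#   c = all other cases with E
#   d = the remainder,
# so a+b+c+d equals the total number of deduplicated cases at every event.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d nonnegative integer cell counts: `a` target drug with
#'   event, `b` target drug without event, `c` other drugs with event, `d`
#'   other drugs without event.
#' @return an object of class `contingency_table` (named list a, b, c, d, n).
#' @export
contingency_table <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
    stop_config("contingency_table: cells must be nonnegative integers")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Build per-event contingency tables from deduplicated cases
#'
#' At `level = "pt"` events are reaction Preferred Terms; at `level =
#' "soc"` each case's PTs are first mapped to their primary System Organ
#' Class, and a case counts once per SOC it hits.
#'
#' @param cases a `faers_cases` object (already deduplicated).
#' @param target_drug_synonyms synonym set defining the target drug.
#' @param level `"pt"` or `"soc"`.
#' @param mapping a `pt_soc_table`; required when `level = "soc"`.
#' @return data frame with columns `event`, `a`, `b`, `c`, `d`, `n`, one
#'   row per event label, sorted by label.
#' @export
build_contingency_tables <- function(cases, target_drug_synonyms,
                                     level = c("pt", "soc"), mapping = NULL) {
  level <- match.arg(level)
  if (level == "soc" && is.null(mapping))
    stop_config("build_contingency_tables: level 'soc' requires a PT-SOC mapping")
  ps <- ps_case_ids(cases, target_drug_synonyms)
  ev <- cases$reac[, c("primaryid", "pt")]
  names(ev)[2] <- "event"
  if (level == "soc") {
    ev$event <- soc_of(ev$event, mapping, policy = "primary_only")
    ev <- unique(ev)
  }
  n_total <- nrow(cases$demo)
  n_ps <- length(ps)
  exposed <- ev$primaryid %in% ps
  a <- tapply(exposed, ev$event, sum)
  with_event <- tapply(exposed, ev$event, length)
  events <- sort(names(a))
  a <- as.numeric(a[events])
  with_event <- as.numeric(with_event[events])
  data.frame(event = events,
             a = a,
             b = n_ps - a,
             c = with_event - a,
             d = n_total - n_ps - (with_event - a),
             n = n_total,
             stringsAsFactors = FALSE)
}
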