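# End-to-end orchestration: ingest -> deduplicate -> primary-suspect filter
# -> contingency tables -> disproportionality -> ranking, with Table-style
# summaries, stage-count logging and plot-data export.

#' Run the full signal-detection pipeline
#'
#' Accepts a directory of quarterly ASCII files, a `faers_report_set`
#' (in-memory simulation) or a pre-assembled `faers_cases` object. Stages:
#' ingestion, case deduplication, primary-suspect filtering on the target
#' drug synonyms, per-event 2x2 tables at PT or SOC level, the four
#' disproportionality statistics with signal flags, and ranking by EBGM.
#' Demographic summaries are computed on the primary-suspect subset.
#'
#' @param input directory path, `faers_report_set`, or `faers_cases`.
#' @param drug_synonyms synonym set for the target drug.
#' @param level `"pt"` or `"soc"`.
#' @param mapping a `pt_soc_table` (required for `level = "soc"`).
#' @param criteria a [signal_criteria()] object.
#' @param mgps `"fit"` or a fixed [mgps_prior()].
#' @param top_n optionally truncate the ranked results.
#' @param output_dir if given, results and summaries are written there as
#'   CSV (plus a plain-text run log).
#' @return list of class `faers_analysis`: `results` (ranked data frame),
#'   `summaries` ([demographic_summary()] of the PS subset), `counts`
#'   (stage counts), `ps_cases`.
#' @export
run_signal_analysis <- function(input, drug_synonyms, level = c("pt", "soc"),
                                mapping = NULL, criteria = signal_criteria(),
                                mgps = "fit", top_n = NULL, output_dir = NULL) {
  level <- match.arg(level)
  cases <- if (inherits(input, "faers_cases")) input
           else if (inherits(input, "faers_report_set")) assemble_cases(input)
           else assemble_cases(read_faers_quarter(input))
  ps_cases <- filter_primary_suspect(cases, drug_synonyms)
  if (nrow(ps_cases$demo) == 0)
    stop(errorCondition(
      "run_signal_analysis: no case lists the target drug as primary suspect",
      class = c("faersignal_empty_result", "error")))
  tables <- build_contingency_tables(cases, drug_synonyms, level = level,
                                     mapping = mapping)
  results <- disproportionality(tables, mgps = mgps, criteria = criteria)
  results <- rank_results(results, key = "ebgm", top_n = top_n)
  counts <- c(raw_demo_rows = cases$log$raw_demo_rows,
              dropped_versions = cases$log$dropped_versions,
              deduplicated_cases = cases$log$n_cases,
              ps_cases = nrow(ps_cases$demo))
  stopifnot(counts[["deduplicated_cases"]] + counts[["dropped_versions"]] ==
              counts[["raw_demo_rows"]])
  summaries <- demographic_summary(ps_cases)
  out <- structure(list(results = results, summaries = summaries,
                        counts = counts, ps_cases = ps_cases),
                   class = "faers_analysis")
  if (!is.null(output_dir)) write_analysis(out, output_dir)
  out
}

#' @export
print.faers_analysis <- function(x, ...) {
  cat("<faers_analysis>\n")
  cat("  raw demo rows:", x$counts[["raw_demo_rows"]],
      "| deduplicated:", x$counts[["deduplicated_cases"]],
      "| primary-suspect:", x$counts[["ps_cases"]], "\n")
  cat("  events analyzed:", nrow(x$results),
      "| any-algorithm signals:", sum(x$results$any_of), "\n")
  invisible(x)
}

write_analysis <- function(analysis, output_dir) {
  if (!dir.exists(output_dir) && !dir.create(output_dir, recursive = TRUE))
    stop_ingest("write_analysis: cannot create ", output_dir)
  utils::write.csv(analysis$results, file.path(output_dir, "signal_results.csv"),
                   row.names = FALSE)
  for (nm in names(analysis$summaries$tables))
    utils::write.csv(analysis$summaries$tables[[nm]],
                     file.path(output_dir, paste0("summary_", nm, ".csv")),
                     row.names = FALSE)
  log_lines <- c(sprintf("raw_demo_rows %d", analysis$counts[["raw_demo_rows"]]),
                 sprintf("dropped_versions %d", analysis$counts[["dropped_versions"]]),
                 sprintf("deduplicated_cases %d", analysis$counts[["deduplicated_cases"]]),
                 sprintf("ps_cases %d", analysis$counts[["ps_cases"]]))
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  pd <- export_plot_data(analysis$results)
  utils::write.csv(pd$waterfall, file.path(output_dir, "waterfall.csv"),
                   row.names = FALSE)
  utils::write.csv(pd$volcano, file.path(output_dir, "volcano.csv"),
                   row.names = FALSE)
  invisible(output_dir)
}

#' Export waterfall and volcano plot data
#'
#' Waterfall: events sorted descending by the chosen intensity column
#' (default `ebgm`). Volcano: `log_ror = ln(ROR)` against
#' `neg_log10_p = -log10` of the upper-tail probability of the Yates
#' chi-square on 1 degree of freedom. Rows with undefined statistics are
#' excluded, with the count reported via a message.
#'
#' @param results a disproportionality results data frame.
#' @param intensity column used for the waterfall ordering.
#' @return list with data frames `waterfall` and `volcano`.
#' @export
export_plot_data <- function(results, intensity = "ebgm") {
  ranked <- rank_results(results, key = intensity)
  keep_w <- !is.na(ranked[[intensity]])
  waterfall <- ranked[keep_w, c("event", "case_reports", intensity)]
  rownames(waterfall) <- NULL
  keep_v <- !is.na(results$ror) & !is.na(results$chisq)
  dropped <- sum(!keep_v)
  if (dropped > 0)
    message(dropped, " event(s) with undefined ROR/chi-square excluded from volcano data")
  volcano <- data.frame(
    event = results$event[keep_v],
    log_ror = log(results$ror[keep_v]),
    neg_log10_p = -log10(stats::pchisq(results$chisq[keep_v], df = 1,
                                       lower.tail = FALSE)))
  list(waterfall = waterfall, volcano = volcano)
}
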