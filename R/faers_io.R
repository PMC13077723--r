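# Ingestion of FAERS-style quarterly ASCII tables: parsing, case
# deduplication, primary-suspect filtering, and per-case assembly.

faers_file_specs <- list(
  demo = list(prefix = "DEMO",
              numeric = c("caseid", "caseversion", "fda_dt", "event_dt", "age", "wt")),
  drug = list(prefix = "DRUG", numeric = "drug_seq"),
  reac = list(prefix = "REAC", numeric = character(0)),
  outc = list(prefix = "OUTC", numeric = character(0)),
  rpsr = list(prefix = "RPSR", numeric = character(0)),
  ther = list(prefix = "THER", numeric = c("dsg_drug_seq", "start_dt"))
)

parse_dollar_file <- function(path, numeric_cols, max_malformed = 0.01) {
  lines <- readLines(path)
  if (length(lines) < 1) stop_ingest("empty file: ", path)
  fields <- strsplit(lines, "$", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  nf <- lengths(body)
  # a trailing empty field is dropped by strsplit; pad rows short by exactly
  # the trailing-blank amount up to the header width
  ok <- nf == length(header)
  padded <- nf < length(header)
  if (any(padded)) {
    body[padded] <- lapply(body[padded], function(f)
      c(f, rep("", length(header) - length(f))))
    ok[padded] <- TRUE
  }
  malformed <- which(!ok)
  if (length(malformed) > max_malformed * max(1, length(body)))
    stop_ingest("parse error in ", basename(path), ": ",
                length(malformed), " malformed row(s) at line(s) ",
                paste(utils::head(malformed + 1L, 10), collapse = ", "))
  if (length(malformed)) {
    warning(sprintf("%s: dropped %d malformed row(s)", basename(path),
                    length(malformed)))
    body <- body[ok]
  }
  m <- matrix(unlist(body, use.names = FALSE), ncol = length(header), byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- header
  out[out == ""] <- NA
  for (col in intersect(numeric_cols, names(out)))
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  attr(out, "malformed_rows") <- length(malformed)
  out
}

#' Read one quarter of FAERS-style ASCII files
#'
#' Expects $-delimited files `DEMO*.txt`, `DRUG*.txt`, `REAC*.txt`,
#' `OUTC*.txt`, `RPSR*.txt`, `THER*.txt` in `directory`. Rows with the
#' wrong field count are counted; parsing fails if they exceed
#' `max_malformed` of a file's rows, otherwise they are dropped with a
#' warning (never silently).
#'
#' @param directory directory holding the quarter's files.
#' @param quarter optional quarter label (e.g. `"17Q4"`) to select among
#'   multiple quarters in one directory.
#' @param max_malformed tolerated proportion of malformed rows per file.
#' @return named list of raw data frames (`demo`, `drug`, `reac`, `outc`,
#'   `rpsr`, `ther`).
#' @export
read_faers_quarter <- function(directory, quarter = NULL, max_malformed = 0.01) {
  if (!dir.exists(directory))
    stop_ingest("read_faers_quarter: no such directory: ", directory)
  out <- list()
  for (nm in names(faers_file_specs)) {
    spec <- faers_file_specs[[nm]]
    pattern <- paste0("^", spec$prefix, if (is.null(quarter)) ".*" else quarter,
                      "\\.txt$")
    hits <- list.files(directory, pattern = pattern, full.names = TRUE)
    if (length(hits) == 0)
      stop_ingest("read_faers_quarter: missing ", spec$prefix, " file in ", directory)
    parts <- lapply(hits, parse_dollar_file, numeric_cols = spec$numeric,
                    max_malformed = max_malformed)
    out[[nm]] <- do.call(rbind, parts)
  }
  out
}

#' Normalize reported ages to years
#'
#' FAERS ages come with a unit code. Recognized codes: `YR` (years), `DEC`
#' (decades), `MON` (months), `WK` (weeks), `DY` (days), `HR` (hours).
#' Unrecognized codes or missing values yield `NA`.
#'
#' @param age numeric age values.
#' @param age_cod character unit codes.
#' @return numeric vector of ages in years.
#' @export
normalize_age_years <- function(age, age_cod) {
  factor_for <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
                  DY = 1 / 365.25, HR = 1 / (24 * 365.25))
  f <- factor_for[toupper(trimws(as.character(age_cod)))]
  as.numeric(age) * as.numeric(f)
}

#' Deduplicate case versions
#'
#' FAERS re-publishes updated versions of a case; only the latest should be
#' counted. Among rows sharing a `caseid`, the retained row maximizes
#' `(caseversion, fda_dt, primaryid)` lexicographically. Output is sorted
#' by `caseid`, so the operation is deterministic and idempotent.
#'
#' @param demo raw demographic data frame (one row per case version).
#' @return deduplicated data frame with attribute `dropped_versions`.
#' @export
deduplicate_cases <- function(demo) {
  if (nrow(demo) == 0) {
    attr(demo, "dropped_versions") <- 0L
    return(demo)
  }
  o <- order(demo$caseid, demo$caseversion, demo$fda_dt, demo$primaryid)
  demo <- demo[o, , drop = FALSE]
  keep <- !duplicated(demo$caseid, fromLast = TRUE)
  out <- demo[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_versions") <- sum(!keep)
  out
}

#' Time to onset in days
#'
#' Whole days from therapy start to event onset. Missing if either date is
#' missing or unparseable; negative intervals are implausible (the event
#' predates therapy) and are returned as missing rather than zero, with the
#' count recorded in attribute `implausible`.
#'
#' @param therapy_start,event_date dates as `Date` or yyyymmdd integers.
#' @return integer vector of days with attribute `implausible`.
#' @export
compute_tto <- function(therapy_start, event_date) {
  s <- if (inherits(therapy_start, "Date")) therapy_start else yyyymmdd_to_date(therapy_start)
  e <- if (inherits(event_date, "Date")) event_date else yyyymmdd_to_date(event_date)
  d <- as.integer(e - s)
  implausible <- sum(d < 0, na.rm = TRUE)
  d[!is.na(d) & d < 0] <- NA
  attr(d, "implausible") <- implausible
  d
}

#' Assemble deduplicated cases from raw quarterly tables
#'
#' Deduplicates the demographic table, restricts the drug/reaction/outcome
#' tables to the retained case versions, normalizes ages to years, derives
#' the reporting year, and computes time to onset from the therapy start
#' date of the case's primary-suspect drug. Reaction PTs are made unique
#' within a case.
#'
#' @param raw list of raw tables as returned by [read_faers_quarter()] (a
#'   `faers_report_set` is accepted too).
#' @return an object of class `faers_cases`: list with `demo` (one row per
#'   case, with `age_years`, `year`, `tto_days`), `drug`, `reac`, `outc`
#'   and a `log` of stage counts.
#' @export
assemble_cases <- function(raw) {
  demo_raw_rows <- nrow(raw$demo)
  demo <- deduplicate_cases(raw$demo)
  dropped <- attr(demo, "dropped_versions")
  keep <- demo$primaryid
  drug <- raw$drug[raw$drug$primaryid %in% keep, , drop = FALSE]
  reac <- raw$reac[raw$reac$primaryid %in% keep, , drop = FALSE]
  reac$pt <- trimws(reac$pt)
  reac <- reac[!is.na(reac$pt) & nzchar(reac$pt), , drop = FALSE]
  reac <- unique(reac[, c("primaryid", "pt")])
  rownames(reac) <- NULL
  outc <- raw$outc[raw$outc$primaryid %in% keep, , drop = FALSE]

  demo$age_years <- normalize_age_years(demo$age, demo$age_cod)
  demo$year <- demo$fda_dt %/% 10000

  # therapy start of the PS drug (first PS row per case)
  ps_rows <- drug[drug$role_cod == "PS", , drop = FALSE]
  ps_first <- ps_rows[!duplicated(ps_rows$primaryid), , drop = FALSE]
  ther <- raw$ther
  ther_key <- paste(ther$primaryid, ther$dsg_drug_seq)
  ps_key <- paste(ps_first$primaryid, ps_first$drug_seq)
  start_dt <- ther$start_dt[match(ps_key, ther_key)]
  start_for_case <- start_dt[match(demo$primaryid, ps_first$primaryid)]
  tto <- compute_tto(start_for_case, demo$event_dt)
  demo$tto_days <- tto

  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 log = list(raw_demo_rows = demo_raw_rows,
                            dropped_versions = dropped,
                            n_cases = nrow(demo),
                            implausible_tto = attr(tto, "implausible"))),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases>", x$log$n_cases, "deduplicated case(s);",
      x$log$dropped_versions, "version(s) dropped\n")
  invisible(x)
}

# primaryids of cases where a synonym-matched drug holds the PS role
ps_case_ids <- function(cases, drug_synonyms) {
  syn <- normalize_drugname(drug_synonyms)
  d <- cases$drug
  hit <- d$role_cod == "PS" & normalize_drugname(d$drugname) %in% syn
  unique(d$primaryid[hit])
}

#' Filter cases where the target drug is the primary suspect
#'
#' Keeps exactly the cases having at least one drug row with role `PS`
#' whose normalized name (uppercased, trimmed, inner whitespace collapsed)
#' is in the synonym set. Matching is exact on normalized names.
#'
#' @param cases a `faers_cases` object.
#' @param drug_synonyms nonempty character vector, e.g.
#'   `c("TORADOL", "KETOROLAC", "KETOROLAC TROMETHAMINE")`.
#' @return a `faers_cases` object restricted to the matching cases.
#' @export
filter_primary_suspect <- function(cases, drug_synonyms) {
  if (length(drug_synonyms) == 0)
    stop_config("filter_primary_suspect: drug_synonyms must be nonempty")
  keep <- ps_case_ids(cases, drug_synonyms)
  out <- cases
  out$demo <- cases$demo[cases$demo$primaryid %in% keep, , drop = FALSE]
  out$drug <- cases$drug[cases$drug$primaryid %in% keep, , drop = FALSE]
  out$reac <- cases$reac[cases$reac$primaryid %in% keep, , drop = FALSE]
  out$outc <- cases$outc[cases$outc$primaryid %in% keep, , drop = FALSE]
  out$log$n_cases <- nrow(out$demo)
  out$log$ps_cases <- nrow(out$demo)
  out
}
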