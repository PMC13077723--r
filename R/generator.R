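# Synthetic spontaneous-report generator.
#
# Emits FAERS-shaped report sets with known ground truth: injected
# drug-event associations of chosen relative risk, duplicate case versions,
# and field-level missingness. Every downstream stage (ingestion, dedup,
# primary-suspect filtering, contingency tables, disproportionality) can be
# validated against the generator's ledger without any external download.

#' Specify an injected drug-event association
#'
#' In reports where drug `drug_id` holds the primary-suspect (PS) role, the
#' probability of event `event_id` is multiplied by `relative_risk` (capped
#' at 1). A relative risk of 1 injects nothing; values above 1 create a true
#' signal the pipeline should recover.
#'
#' @param drug_id,event_id 1-based indices into the generator vocabularies.
#' @param relative_risk nonnegative multiplier on the event's base rate.
#' @return an object of class `faers_signal_spec`.
#' @export
signal_spec <- function(drug_id, event_id, relative_risk) {
  if (!is.numeric(relative_risk) || length(relative_risk) != 1 || relative_risk < 0)
    stop_config("signal_spec: relative_risk must be a single nonnegative number")
  structure(list(drug_id = as.integer(drug_id), event_id = as.integer(event_id),
                 relative_risk = as.numeric(relative_risk)),
            class = "faers_signal_spec")
}

#' Default demographic marginals for the generator
#'
#' Categorical distributions for sex, age band, weight band, reporter
#' occupation, reporting country, administration route and outcome code,
#' calibrated to the published ketorolac (Toradol) report profile so that
#' simulated corpora resemble the study conditions. Each marginal is a named
#' probability vector over the non-missing categories; missingness is
#' applied separately (see [generator_config()]).
#'
#' @return named list of named probability vectors.
#' @export
default_demographic_marginals <- function() {
  norm <- function(x) x / sum(x)
  list(
    sex = norm(c(F = 242, M = 113)),
    age_band = norm(c("<18" = 9, "18-45" = 89, "45-65" = 88,
                      "65-75" = 32, ">=75" = 42)),
    weight_band = norm(c("<60" = 27, "60-80" = 55, ">=80" = 55)),
    reporter = norm(c(CN = 106, MD = 79, OT = 76, PH = 45, LW = 3, RN = 1)),
    country = norm(c(US = 120, OTHER = 34)),
    route = norm(c(OTHER = 176, INTRAMUSCULAR = 69, INTRAVENOUS = 65, ORAL = 45)),
    outcome = norm(c(HO = 143, OT = 108, LT = 46, DE = 33, DS = 24, RI = 19, CA = 1))
  )
}

default_missingness <- function() {
  c(sex = 0.058, age = 0.268, weight = 0.614, reporter = 0.127,
    country = 0.592, route = 0.058, therapy_start = 0.157, outcome = 0.008)
}

#' Configure the synthetic report generator
#'
#' @param n_reports number of true (pre-duplication) cases, >= 1.
#' @param n_drugs,n_events vocabulary sizes.
#' @param drug_prevalence per-drug probability that a report mentions the
#'   drug (recycled to `n_drugs`).
#' @param event_base_rate per-event baseline probability per report
#'   (recycled to `n_events`). Each event is an independent Bernoulli draw
#'   per case, so the sum of base rates is the expected number of reaction
#'   terms per case.
#' @param injected_signals list of [signal_spec()] objects.
#' @param duplicate_fraction proportion in \[0, 1) of cases re-emitted as a
#'   later case version (same `caseid`, `caseversion` 2, later receipt
#'   date; all other fields identical).
#' @param missingness named probabilities of a blank field, for fields
#'   `sex`, `age`, `weight`, `reporter`, `country`, `route`,
#'   `therapy_start`, `outcome`.
#' @param demographic_marginals named list as returned by
#'   [default_demographic_marginals()].
#' @param tto_distribution named probability vector over time-to-onset
#'   buckets `<7`, `7-28`, `28-60`, `>=60` (days from therapy start).
#' @param seed integer RNG seed; all randomness derives from it.
#' @return an object of class `faers_generator_config`.
#' @export
generator_config <- function(n_reports = 10000,
                             n_drugs = 25,
                             n_events = 160,
                             drug_prevalence = 0.05,
                             event_base_rate = 0.01,
                             injected_signals = list(),
                             duplicate_fraction = 0,
                             missingness = default_missingness(),
                             demographic_marginals = default_demographic_marginals(),
                             tto_distribution = c("<7" = 144, "7-28" = 12,
                                                  "28-60" = 5, ">=60" = 5) / 166,
                             seed = 1L) {
  if (!is.numeric(n_reports) || n_reports < 1)
    stop_config("generator_config: n_reports must be >= 1")
  n_drugs <- as.integer(n_drugs); n_events <- as.integer(n_events)
  prev <- rep_len(as.numeric(drug_prevalence), n_drugs)
  base <- rep_len(as.numeric(event_base_rate), n_events)
  if (any(prev < 0 | prev > 1))
    stop_config("generator_config: drug_prevalence must lie in [0, 1]")
  if (any(base < 0 | base > 1))
    stop_config("generator_config: event_base_rate must lie in [0, 1]")
  if (!is.numeric(duplicate_fraction) || duplicate_fraction < 0 || duplicate_fraction >= 1)
    stop_config("generator_config: duplicate_fraction must lie in [0, 1)")
  miss <- default_missingness()
  miss[names(missingness)] <- as.numeric(missingness)
  if (any(miss < 0 | miss > 1))
    stop_config("generator_config: missingness probabilities must lie in [0, 1]")
  for (nm in names(demographic_marginals)) {
    m <- demographic_marginals[[nm]]
    if (any(m < 0) || abs(sum(m) - 1) > 1e-9)
      stop_config("generator_config: demographic marginal '", nm,
                  "' must be nonnegative and sum to 1")
  }
  if (abs(sum(tto_distribution) - 1) > 1e-9 || any(tto_distribution < 0))
    stop_config("generator_config: tto_distribution must be a probability vector")
  if (!setequal(names(tto_distribution), c("<7", "7-28", "28-60", ">=60")))
    stop_config("generator_config: tto_distribution buckets must be <7, 7-28, 28-60, >=60")
  for (s in injected_signals) {
    if (!inherits(s, "faers_signal_spec"))
      stop_config("generator_config: injected_signals must be signal_spec objects")
    if (s$drug_id < 1 || s$drug_id > n_drugs)
      stop_config("generator_config: injected signal drug_id ", s$drug_id,
                  " outside 1..", n_drugs)
    if (s$event_id < 1 || s$event_id > n_events)
      stop_config("generator_config: injected signal event_id ", s$event_id,
                  " outside 1..", n_events)
  }
  structure(list(
    n_reports = as.integer(n_reports), n_drugs = n_drugs, n_events = n_events,
    drug_prevalence = prev, event_base_rate = base,
    injected_signals = injected_signals,
    duplicate_fraction = as.numeric(duplicate_fraction),
    missingness = miss,
    demographic_marginals = demographic_marginals,
    tto_distribution = tto_distribution,
    seed = as.integer(seed)
  ), class = "faers_generator_config")
}

# vocabulary labels
generator_drug_names <- function(n) sprintf("DRUG_%02d", seq_len(n))
generator_event_names <- function(n) sprintf("EVENT_%03d", seq_len(n))

# Reaction term used when a case draws no event at all; kept outside the
# modeled vocabulary so it never perturbs any (drug, event) contingency cell.
FILLER_PT <- "Drug ineffective"

#' Generate a synthetic FAERS-style report set
#'
#' For each case: drugs are included as independent Bernoulli draws from
#' `drug_prevalence` (at least one is forced), one included drug is chosen
#' uniformly as primary suspect (PS), and every event occurs as an
#' independent Bernoulli draw from its base rate, multiplied by the injected
#' relative risk when the case's PS drug matches an injected pair. A case
#' drawing zero events receives a filler reaction term outside the modeled
#' vocabulary, so each modeled event keeps its exact Bernoulli marginal and
#' the generative odds ratio for an injected pair has a closed form.
#' Duplicate case versions and field-level missingness are applied last.
#'
#' @param config a [generator_config()].
#' @return an object of class `faers_report_set`: a list with elements
#'   `demo`, `drug`, `reac`, `outc`, `rpsr`, `ther` (data frames in the
#'   quarterly-file schemas), `truth` (ground-truth ledger: per-case PS drug
#'   and reactions, duplicate caseids, vocabularies) and `config`.
#' @export
generate_reports <- function(config) {
  if (!inherits(config, "faers_generator_config"))
    stop_config("generate_reports: config must come from generator_config()")
  set.seed(config$seed)
  n <- config$n_reports
  nd <- config$n_drugs
  ne <- config$n_events
  drug_names <- generator_drug_names(nd)
  event_names <- generator_event_names(ne)

  ## --- drug inclusion and PS assignment --------------------------------
  inc <- matrix(runif(n * nd) < rep(config$drug_prevalence, each = n), n, nd)
  none <- which(rowSums(inc) == 0)
  if (length(none))
    inc[cbind(none, sample.int(nd, length(none), replace = TRUE))] <- TRUE
  key <- matrix(runif(n * nd), n, nd)
  key[!inc] <- -1
  ps_drug <- max.col(key, ties.method = "first")

  ## --- reactions --------------------------------------------------------
  ev <- matrix(FALSE, n, ne)
  for (e in seq_len(ne)) {
    p <- rep(config$event_base_rate[e], n)
    for (s in config$injected_signals) {
      if (s$event_id == e)
        p[ps_drug == s$drug_id] <- min(1, s$relative_risk * config$event_base_rate[e])
    }
    ev[, e] <- runif(n) < p
  }
  no_event <- rowSums(ev) == 0

  ## --- identifiers and dates -------------------------------------------
  caseid <- 10000000L + seq_len(n)
  primaryid <- paste0(caseid, 1L)
  fda_date <- as.Date("2004-01-01") + sample.int(5113L, n, replace = TRUE) - 1L
  event_date <- fda_date

  ## --- demographics -----------------------------------------------------
  mg <- config$demographic_marginals
  sex <- sample_categorical(n, mg$sex)
  age_band <- sample_categorical(n, mg$age_band)
  age <- round(stats::runif(n,
    min = c("<18" = 1, "18-45" = 18, "45-65" = 45, "65-75" = 65, ">=75" = 75)[age_band],
    max = c("<18" = 18, "18-45" = 45, "45-65" = 65, "65-75" = 75, ">=75" = 95)[age_band]), 1)
  wt_band <- sample_categorical(n, mg$weight_band)
  wt <- round(stats::runif(n,
    min = c("<60" = 40, "60-80" = 60, ">=80" = 80)[wt_band],
    max = c("<60" = 60, "60-80" = 80, ">=80" = 120)[wt_band]), 1)
  reporter <- sample_categorical(n, mg$reporter)
  country <- ifelse(sample_categorical(n, mg$country) == "US", "US",
                    sample(c("GB", "CA", "JP", "FR", "DE"), n, replace = TRUE))
  route <- sample_categorical(n, mg$route)
  outcome <- sample_categorical(n, mg$outcome)

  tto_bucket <- sample_categorical(n, config$tto_distribution)
  tto_days <- c(sample(0:6, n, replace = TRUE), sample(7:27, n, replace = TRUE),
                sample(28:59, n, replace = TRUE), sample(60:180, n, replace = TRUE))
  tto_days <- tto_days[seq_len(n) +
    n * (match(tto_bucket, c("<7", "7-28", "28-60", ">=60")) - 1L)]
  start_date <- event_date - tto_days

  ## --- missingness masks ------------------------------------------------
  miss <- config$missingness
  blank <- function(field) runif(n) < miss[[field]]
  sex[blank("sex")] <- NA
  age_missing <- blank("age")
  age[age_missing] <- NA
  wt_missing <- blank("weight")
  wt[wt_missing] <- NA
  reporter[blank("reporter")] <- NA
  country[blank("country")] <- NA
  route[blank("route")] <- NA
  ther_missing <- blank("therapy_start")
  outc_missing <- blank("outcome")

  ## --- assemble quarterly tables ---------------------------------------
  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = 1L,
    fda_dt = date_to_yyyymmdd(fda_date), event_dt = date_to_yyyymmdd(event_date),
    sex = sex, age = age,
    age_cod = ifelse(is.na(age), NA, "YR"),
    wt = wt, wt_cod = ifelse(is.na(wt), NA, "KG"),
    occp_cod = reporter, occr_country = country,
    stringsAsFactors = FALSE)

  drug_idx <- which(inc, arr.ind = TRUE)
  drug_idx <- drug_idx[order(drug_idx[, 1], drug_idx[, 2]), , drop = FALSE]
  drug_case <- drug_idx[, 1]
  drug_id <- drug_idx[, 2]
  is_ps <- drug_id == ps_drug[drug_case]
  role <- ifelse(is_ps, "PS",
                 sample(c("SS", "C", "I"), nrow(drug_idx), replace = TRUE,
                        prob = c(0.3, 0.6, 0.1)))
  drug_seq <- sequence(rle(drug_case)$lengths)
  drug <- data.frame(
    primaryid = primaryid[drug_case], drug_seq = drug_seq, role_cod = role,
    drugname = drug_names[drug_id],
    route = route[drug_case],
    stringsAsFactors = FALSE)

  reac_idx <- which(ev, arr.ind = TRUE)
  reac_idx <- reac_idx[order(reac_idx[, 1], reac_idx[, 2]), , drop = FALSE]
  reac <- data.frame(primaryid = c(primaryid[reac_idx[, 1]], primaryid[no_event]),
                     pt = c(event_names[reac_idx[, 2]], rep(FILLER_PT, sum(no_event))),
                     stringsAsFactors = FALSE)
  reac <- reac[order(reac$primaryid), , drop = FALSE]
  rownames(reac) <- NULL

  outc <- data.frame(primaryid = primaryid[!outc_missing],
                     outc_cod = outcome[!outc_missing], stringsAsFactors = FALSE)
  rpsr <- data.frame(primaryid = primaryid,
                     rpsr_cod = sample(c("CSM", "HP", "FGN", "LIT", "OTH"), n,
                                       replace = TRUE, prob = c(.35, .35, .1, .05, .15)),
                     stringsAsFactors = FALSE)
  ps_seq <- drug_seq[is_ps][order(drug_case[is_ps])]
  ther <- data.frame(primaryid = primaryid[!ther_missing],
                     dsg_drug_seq = ps_seq[!ther_missing],
                     start_dt = date_to_yyyymmdd(start_date)[!ther_missing],
                     stringsAsFactors = FALSE)

  ## --- duplicate case versions -----------------------------------------
  n_dup <- floor(config$duplicate_fraction * n)
  dup_caseids <- integer(0)
  if (n_dup > 0) {
    di <- sort(sample.int(n, n_dup))
    dup_caseids <- caseid[di]
    old_id <- primaryid[di]
    new_id <- paste0(caseid[di], 2L)
    demo2 <- demo[di, , drop = FALSE]
    demo2$primaryid <- new_id
    demo2$caseversion <- 2L
    demo2$fda_dt <- date_to_yyyymmdd(fda_date[di] + sample.int(91L, n_dup, replace = TRUE) - 1L)
    demo <- rbind(demo, demo2)
    relabel <- function(tab) {
      sub <- tab[tab$primaryid %in% old_id, , drop = FALSE]
      sub$primaryid <- new_id[match(sub$primaryid, old_id)]
      rbind(tab, sub)
    }
    drug <- relabel(drug); reac <- relabel(reac); outc <- relabel(outc)
    rpsr <- relabel(rpsr); ther <- relabel(ther)
  }

  truth <- list(
    cases = data.frame(caseid = caseid, primaryid = primaryid,
                       ps_drug_id = ps_drug, stringsAsFactors = FALSE),
    reactions = data.frame(caseid = caseid[reac_idx[, 1]],
                           event_id = as.integer(reac_idx[, 2])),
    duplicate_caseids = dup_caseids,
    drug_names = drug_names, event_names = event_names)

  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 rpsr = rpsr, ther = ther, truth = truth, config = config),
            class = "faers_report_set")
}

#' @export
print.faers_report_set <- function(x, ...) {
  cat("<faers_report_set>\n")
  cat("  cases (pre-duplication):", x$config$n_reports, "\n")
  cat("  demo rows:", nrow(x$demo), " drug rows:", nrow(x$drug),
      " reaction rows:", nrow(x$reac), "\n")
  cat("  injected signals:", length(x$config$injected_signals), "\n")
  invisible(x)
}

#' Ground-truth contingency table for a generated pair
#'
#' Direct enumeration over the generator's pre-duplication ledger: `a` =
#' cases whose PS drug is `drug_id` and that carry `event_id`; `b`, `c`,
#' `d` complete the 2x2 layout over all cases. Bypasses file I/O and
#' deduplication, serving as the oracle for [build_contingency_tables()].
#'
#' @param report_set a `faers_report_set`.
#' @param drug_id,event_id vocabulary indices.
#' @return a [contingency_table()].
#' @export
true_contingency <- function(report_set, drug_id, event_id) {
  if (!inherits(report_set, "faers_report_set"))
    stop_config("true_contingency: report_set must come from generate_reports()")
  if (drug_id < 1 || drug_id > report_set$config$n_drugs)
    stop_config("true_contingency: unknown drug_id ", drug_id)
  if (event_id < 1 || event_id > report_set$config$n_events)
    stop_config("true_contingency: unknown event_id ", event_id)
  cases <- report_set$truth$cases
  reac <- report_set$truth$reactions
  exposed <- cases$ps_drug_id == drug_id
  with_event <- cases$caseid %in% reac$caseid[reac$event_id == event_id]
  contingency_table(a = sum(exposed & with_event),
                    b = sum(exposed & !with_event),
                    c = sum(!exposed & with_event),
                    d = sum(!exposed & !with_event))
}

#' Write a report set in the quarterly ASCII dialect
#'
#' Emits DEMO/DRUG/REAC/OUTC/RPSR/THER files, $-delimited with one header
#' line, named like `DEMO17Q4.txt`. Missing values are written as empty
#' fields. [read_faers_quarter()] recovers an equivalent raw-table set.
#'
#' @param report_set a `faers_report_set`.
#' @param directory output directory (created if needed).
#' @param quarter_label label such as `"17Q4"` used in file names.
#' @return invisibly, a manifest data frame (file, rows).
#' @export
write_faers_ascii <- function(report_set, directory, quarter_label = "17Q4") {
  if (!dir.exists(directory) && !dir.create(directory, recursive = TRUE))
    stop_ingest("write_faers_ascii: cannot create directory ", directory)
  tables <- c("demo", "drug", "reac", "outc", "rpsr", "ther")
  files <- file.path(directory, paste0(toupper(tables), quarter_label, ".txt"))
  for (i in seq_along(tables)) {
    utils::write.table(report_set[[tables[i]]], files[i], sep = "$",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(data.frame(file = files,
                       rows = vapply(tables, function(t) nrow(report_set[[t]]), 0L)))
}
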