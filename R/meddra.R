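# Preferred Term (PT) -> System Organ Class (SOC) mapping.
#
# MedDRA itself is licensed and is not shipped; the module consumes a plain
# two-column surrogate table (pt, soc, is_primary) with the same semantics:
# a PT may map to several SOCs (multi-axiality) but has exactly one primary
# SOC.

#' The 21 System Organ Class names
#'
#' Target vocabulary for SOC-level aggregation.
#' @return character vector of length 21.
#' @export
soc_names <- function() c(
  "Immune system disorders",
  "Renal and urinary disorders",
  "Gastrointestinal disorders",
  "Vascular disorders",
  "Respiratory, thoracic, and mediastinal disorders",
  "Ear and labyrinth disorders",
  "Blood and lymphatic system disorders",
  "Skin and subcutaneous tissue disorders",
  "Nervous system disorders",
  "Psychiatric disorders",
  "Musculoskeletal and connective tissue disorders",
  "Pregnancy, puerperium, and perinatal conditions",
  "Investigations",
  "Reproductive system and breast disorders",
  "Cardiac disorders",
  "General disorders and administration site conditions",
  "Hepatobiliary disorders",
  "Metabolism and nutrition disorders",
  "Injury, poisoning, and procedural complications",
  "Eye disorders",
  "Infections and infestations")

validate_pt_soc <- function(tab) {
  required <- c("pt", "soc", "is_primary")
  if (!all(required %in% names(tab)))
    stop_config("PT-SOC mapping must have columns pt, soc, is_primary")
  tab$pt <- trimws(tab$pt)
  tab$soc <- trimws(tab$soc)
  tab$is_primary <- as.logical(tab$is_primary)
  dup <- duplicated(tab[, c("pt", "soc")])
  if (any(dup))
    stop_config("PT-SOC mapping: duplicate (pt, soc) pair(s) at row(s) ",
                paste(which(dup), collapse = ", "))
  n_primary <- tapply(tab$is_primary, tab$pt, sum)
  bad <- names(n_primary)[n_primary != 1]
  if (length(bad))
    stop_config("PT-SOC mapping: PT(s) without exactly one primary SOC: ",
                paste(utils::head(bad, 10), collapse = ", "))
  class(tab) <- c("pt_soc_table", "data.frame")
  tab
}

#' Load a PT-to-SOC mapping table
#'
#' @param path CSV file with columns `pt`, `soc`, `is_primary`.
#' @return a validated `pt_soc_table` data frame.
#' @export
load_pt_soc_mapping <- function(path) {
  if (!file.exists(path)) stop_ingest("load_pt_soc_mapping: no such file: ", path)
  validate_pt_soc(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Build a PT-SOC mapping in memory
#'
#' Convenience constructor used for synthetic vocabularies: assigns each PT
#' a primary SOC (round-robin over [soc_names()] by default).
#'
#' @param pts character vector of PT labels.
#' @param socs SOC vocabulary to cycle over.
#' @return a `pt_soc_table`.
#' @export
pt_soc_mapping <- function(pts, socs = soc_names()) {
  validate_pt_soc(data.frame(
    pt = pts,
    soc = rep_len(socs, length(pts)),
    is_primary = TRUE,
    stringsAsFactors = FALSE))
}

#' Map PTs to their System Organ Class
#'
#' Under `policy = "primary_only"` each PT resolves to its unique primary
#' SOC (vectorized, one SOC per PT); under `"all"` every mapped SOC is
#' returned (a list). PTs absent from the table resolve to the sentinel
#' `"UNMAPPED"` with a warning.
#'
#' @param pt character vector of PTs.
#' @param table a `pt_soc_table`.
#' @param policy `"primary_only"` (default) or `"all"`.
#' @return character vector (primary_only) or named list (all).
#' @export
soc_of <- function(pt, table, policy = c("primary_only", "all")) {
  policy <- match.arg(policy)
  pt <- trimws(pt)
  if (policy == "primary_only") {
    prim <- table[table$is_primary, , drop = FALSE]
    out <- prim$soc[match(pt, prim$pt)]
    unmapped <- is.na(out)
    if (any(unmapped)) {
      warning(sum(unmapped), " PT(s) not in mapping; labelled UNMAPPED")
      out[unmapped] <- "UNMAPPED"
    }
    out
  } else {
    res <- lapply(pt, function(p) {
      s <- table$soc[table$pt == p]
      if (length(s) == 0) "UNMAPPED" else s
    })
    if (any(vapply(res, identical, TRUE, y = "UNMAPPED")))
      warning("some PT(s) not in mapping; labelled UNMAPPED")
    names(res) <- pt
    res
  }
}
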