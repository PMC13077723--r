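test_that("write/read round trip recovers identifiers, roles and PTs", {
  cfg <- generator_config(n_reports = 100, duplicate_fraction = 0.1, seed = 4)
  rs <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_faers_ascii(rs, dir, "17Q4")
  expect_equal(manifest$rows[1], nrow(rs$demo))
  raw <- read_faers_quarter(dir, quarter = "17Q4")
  expect_equal(nrow(raw$demo), nrow(rs$demo))
  expect_equal(sort(raw$demo$primaryid), sort(rs$demo$primaryid))
  expect_equal(raw$demo$caseid[order(raw$demo$primaryid)],
               rs$demo$caseid[order(rs$demo$primaryid)])
  o1 <- order(raw$drug$primaryid, raw$drug$drug_seq)
  o2 <- order(rs$drug$primaryid, rs$drug$drug_seq)
  expect_equal(raw$drug$role_cod[o1], rs$drug$role_cod[o2])
  expect_equal(raw$drug$drugname[o1], rs$drug$drugname[o2])
  expect_equal(sort(paste(raw$reac$primaryid, raw$reac$pt)),
               sort(paste(rs$reac$primaryid, rs$reac$pt)))
})

test_that("missing fields are written as the empty token and read back as NA", {
  cfg <- generator_config(n_reports = 200, seed = 9,
                          missingness = c(sex = 0.5))
  rs <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  write_faers_ascii(rs, dir, "10Q1")
  lines <- readLines(file.path(dir, "DEMO10Q1.txt"))[-1]
  sex_field <- vapply(strsplit(lines, "$", fixed = TRUE), `[`, "", 6)
  expect_equal(sum(sex_field == ""), sum(is.na(rs$demo$sex)))
  raw <- read_faers_quarter(dir)
  expect_equal(sum(is.na(raw$demo$sex)), sum(is.na(rs$demo$sex)))
})

test_that("malformed rows are tolerated below the threshold and fatal above it", {
  cfg <- generator_config(n_reports = 300, seed = 2)
  rs <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  write_faers_ascii(rs, dir, "05Q2")
  reac_path <- file.path(dir, "REAC05Q2.txt")
  cat("too$many$fields$here$x$y\n", file = reac_path, append = TRUE)
  expect_warning(raw <- read_faers_quarter(dir), "malformed")
  expect_equal(nrow(raw$reac), nrow(rs$reac))
  # exceed the tolerance
  cat(rep("a$b$c$d$e$f\n", 50), file = reac_path, append = TRUE, sep = "")
  expect_error(read_faers_quarter(dir), "malformed")
  expect_error(read_faers_quarter(withr::local_tempdir()), "DEMO")
})

test_that("ages are normalized to years by unit code", {
  # hand-computed: 45 YR -> 45; 6 DEC -> 60; 18 MON -> 1.5;
  # 26 WK -> 26*7/365.25; 730.5 DY -> 2
  got <- normalize_age_years(c(45, 6, 18, 26, 730.5),
                             c("YR", "DEC", "MON", "WK", "DY"))
  expect_equal(got, c(45, 60, 1.5, 26 * 7 / 365.25, 2))
  expect_true(is.na(normalize_age_years(10, "XX")))
  expect_true(is.na(normalize_age_years(NA, "YR")))
})

test_that("deduplication keeps the lexicographic maximum of (version, date, id)", {
  demo <- raw_fixture(caseid = c(1, 1, 2, 2, 3),
                      caseversion = c(1L, 2L, 1L, 1L, 1L),
                      fda_dt = c(20100101, 20100301, 20100101, 20100501, 20100101),
                      drugs = rep(list("X"), 5), roles = rep(list("PS"), 5),
                      pts = rep(list("P"), 5))$demo
  demo$primaryid <- c("11", "12", "21a", "21b", "31")
  out <- deduplicate_cases(demo)
  expect_equal(out$primaryid, c("12", "21b", "31"))  # version, then date
  expect_equal(attr(out, "dropped_versions"), 2L)
  # idempotence
  out2 <- deduplicate_cases(out)
  attr(out, "dropped_versions") <- NULL; attr(out2, "dropped_versions") <- NULL
  expect_identical(out2, out)
  expect_equal(nrow(deduplicate_cases(demo[0, ])), 0)
})

test_that("deduplicating a generated set recovers the pre-duplication ledger", {
  cfg <- generator_config(n_reports = 1000, duplicate_fraction = 0.2, seed = 6)
  rs <- generate_reports(cfg)
  cases <- assemble_cases(rs)
  expect_equal(nrow(cases$demo), 1000)
  expect_equal(sort(cases$demo$caseid), sort(rs$truth$cases$caseid))
  # conservation: retained + dropped = raw demo rows
  expect_equal(cases$log$n_cases + cases$log$dropped_versions,
               cases$log$raw_demo_rows)
  # retained rows carry the duplicate's version but the original's content
  orig <- rs$demo[rs$demo$caseversion == 1, ]
  m <- match(cases$demo$caseid, orig$caseid)
  expect_equal(cases$demo$sex, orig$sex[m])
  expect_equal(cases$demo$age, orig$age[m])
})

test_that("primary-suspect filtering matches normalized synonyms and the PS role only", {
  raw <- raw_fixture(caseid = 1:4,
                     drugs = list("TORADOL", c("ASPIRIN", "toradol"),
                                  "  Toradol ", "KETOROLAC  TROMETHAMINE"),
                     roles = list("PS", c("PS", "SS"), "PS", "PS"),
                     pts = list("P1", "P1", "P2", "P3"))
  cases <- assemble_cases(raw)
  syn <- c("TORADOL", "KETOROLAC", "KETOROLAC TROMETHAMINE")
  got <- filter_primary_suspect(cases, syn)
  # case 2 has the drug as SS only -> excluded; 3 normalizes; 4 collapses spaces
  expect_equal(sort(got$demo$caseid), c(1, 3, 4))
  expect_error(filter_primary_suspect(cases, character(0)), "nonempty")
  # monotonicity in the synonym set
  s1 <- filter_primary_suspect(cases, "TORADOL")
  expect_true(all(s1$demo$caseid %in% got$demo$caseid))
})

test_that("primary-suspect subset of a generated corpus equals the ledger", {
  cfg <- generator_config(n_reports = 2000, n_drugs = 8, seed = 31,
                          drug_prevalence = 0.2)
  rs <- generate_reports(cfg)
  cases <- assemble_cases(rs)
  got <- filter_primary_suspect(cases, "DRUG_03")
  want <- rs$truth$cases$caseid[rs$truth$cases$ps_drug_id == 3]
  expect_equal(sort(got$demo$caseid), sort(want))
})

test_that("time to onset is whole days, missing-safe, and rejects negative intervals", {
  expect_equal(as.integer(compute_tto(20100101, 20100101)), 0L)
  expect_equal(as.integer(compute_tto(20100101, 20100108)), 7L)
  neg <- compute_tto(20100110, 20100105)
  expect_true(is.na(neg))
  expect_equal(attr(neg, "implausible"), 1L)
  expect_true(is.na(compute_tto(NA, 20100101)))
  expect_true(is.na(compute_tto(20100101, NA)))
})
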