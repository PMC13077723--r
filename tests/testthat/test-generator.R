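test_that("generation is deterministic for a fixed seed", {
  cfg <- generator_config(n_reports = 500, seed = 3)
  rs1 <- generate_reports(cfg)
  rs2 <- generate_reports(cfg)
  expect_identical(rs1$demo, rs2$demo)
  expect_identical(rs1$drug, rs2$drug)
  expect_identical(rs1$reac, rs2$reac)
  expect_identical(rs1$ther, rs2$ther)
})

test_that("structural guarantees hold: case counts, one PS per case, nonempty rows", {
  cfg <- generator_config(n_reports = 1000, duplicate_fraction = 0, seed = 5)
  rs <- generate_reports(cfg)
  expect_equal(nrow(rs$demo), 1000)
  ps_per_case <- tapply(rs$drug$role_cod == "PS", rs$drug$primaryid, sum)
  expect_true(all(ps_per_case == 1))
  expect_true(all(rs$demo$primaryid %in% rs$drug$primaryid))
  expect_true(all(rs$demo$primaryid %in% rs$reac$primaryid))
})

test_that("duplicates share the caseid with a later version and receipt date", {
  cfg <- generator_config(n_reports = 400, duplicate_fraction = 0.25, seed = 8)
  rs <- generate_reports(cfg)
  expect_equal(nrow(rs$demo), 400 + 100)
  dups <- rs$demo[rs$demo$caseversion == 2, ]
  expect_equal(sort(dups$caseid), sort(rs$truth$duplicate_caseids))
  orig <- rs$demo[match(dups$caseid, rs$demo$caseid), ]
  expect_true(all(dups$fda_dt >= orig$fda_dt))
  # only caseversion, fda_dt and primaryid differ
  shared <- setdiff(names(rs$demo), c("primaryid", "caseversion", "fda_dt"))
  expect_identical(dups[, shared], structure(orig[, shared], row.names = rownames(dups)))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(generator_config(n_reports = 0), "n_reports")
  expect_error(generator_config(duplicate_fraction = 1), "duplicate_fraction")
  expect_error(generator_config(event_base_rate = 1.5), "event_base_rate")
  expect_error(generator_config(injected_signals = list(signal_spec(99, 1, 2))),
               "drug_id")
  expect_error(signal_spec(1, 1, -1), "relative_risk")
  bad_marg <- default_demographic_marginals()
  bad_marg$sex <- c(F = 0.5, M = 0.6)
  expect_error(generator_config(demographic_marginals = bad_marg), "sex")
})

test_that("true_contingency matches a per-case double loop and handles edge cases", {
  # single deterministic case: one drug (PS), one certain event
  cfg1 <- generator_config(n_reports = 1, n_drugs = 1, n_events = 1,
                           drug_prevalence = 1, event_base_rate = 1, seed = 1)
  tt <- true_contingency(generate_reports(cfg1), 1, 1)
  expect_equal(unlist(tt[c("a", "b", "c", "d")]), c(a = 1, b = 0, c = 0, d = 0))

  cfg <- generator_config(n_reports = 300, n_drugs = 4, n_events = 6,
                          drug_prevalence = 0.3, event_base_rate = 0.15, seed = 21)
  rs <- generate_reports(cfg)
  for (d_id in 1:4) for (e_id in c(1, 4)) {
    got <- true_contingency(rs, d_id, e_id)
    want <- loop_contingency(rs, d_id, e_id)
    expect_equal(unlist(got[c("a", "b", "c", "d")]), want)
  }
  expect_error(true_contingency(rs, 99, 1), "drug_id")
  expect_error(true_contingency(rs, 1, 99), "event_id")
})

test_that("a null injection (relative risk 1) yields a ROR consistent with 1", {
  cfg <- generator_config(n_reports = 50000, n_drugs = 10, n_events = 20,
                          drug_prevalence = 0.05, event_base_rate = 0.01,
                          injected_signals = list(signal_spec(2, 3, 1.0)),
                          seed = 13)
  tt <- true_contingency(generate_reports(cfg), 2, 3)
  ci <- ror(data.frame(a = tt$a, b = tt$b, c = tt$c, d = tt$d))
  expect_true(ci$ci_low <= 1 && 1 <= ci$ci_high)
})

test_that("sample ROR of an injected pair covers the analytic generative odds ratio", {
  # event probability 0.10 when exposed vs 0.01 otherwise:
  # OR = (0.1/0.9)/(0.01/0.99) = 11
  cfg <- generator_config(n_reports = 200000, n_drugs = 10, n_events = 20,
                          drug_prevalence = 0.05, event_base_rate = 0.01,
                          injected_signals = list(signal_spec(1, 1, 10)),
                          seed = 1)
  tt <- true_contingency(generate_reports(cfg), 1, 1)
  ci <- ror(data.frame(a = tt$a, b = tt$b, c = tt$c, d = tt$d))
  expect_true(ci$ci_low <= 11 && 11 <= ci$ci_high)
})

test_that("mean sample ROR converges to the analytic odds ratio across replicates", {
  p0 <- 0.02
  for (rr in c(1, 2, 10)) {
    p1 <- min(1, rr * p0)
    analytic <- (p1 / (1 - p1)) / (p0 / (1 - p0))
    rors <- vapply(1:6, function(s) {
      cfg <- generator_config(n_reports = 20000, n_drugs = 5, n_events = 10,
                              drug_prevalence = 0.1, event_base_rate = p0,
                              injected_signals = list(signal_spec(1, 1, rr)),
                              seed = 100 + s)
      tt <- true_contingency(generate_reports(cfg), 1, 1)
      (tt$a * tt$d) / (tt$b * tt$c)
    }, 0)
    mc_se <- sd(rors) / sqrt(length(rors))
    expect_lt(abs(mean(rors) - analytic), 3 * mc_se + 1e-9)
  }
})
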