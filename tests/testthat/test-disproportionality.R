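test_that("ROR point estimate and Wald interval match direct evaluation", {
  t0 <- contingency_table(10, 10, 10, 10)
  r0 <- ror(t0)
  expect_equal(r0$ror, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(log(r0$ci_low), -log(r0$ci_high))
  t1 <- contingency_table(20, 10, 5, 40)
  r1 <- ror(t1)
  expect_equal(r1$ror, 16)
  # frozen from independent direct evaluation of exp(ln16 +/- 1.96...*se)
  expect_equal(r1$ci_low, 4.8180091491896526, tolerance = 1e-12)
  expect_equal(r1$ci_high, 53.133979632034723, tolerance = 1e-12)
  # zero cells are undefined, not corrected
  expect_true(all(is.na(ror(contingency_table(0, 10, 5, 40)))))
  expect_false(any(is.na(ror(contingency_table(0, 10, 5, 40), haldane = TRUE))))
})

test_that("PRR point estimate and log-Wald interval match direct evaluation", {
  expect_equal(prr(contingency_table(10, 10, 10, 10))$prr, 1)
  p <- prr(contingency_table(20, 10, 5, 40))
  expect_equal(p$prr, 6)  # 20*45 / (5*30)
  expect_equal(p$ci_low, 2.5281721946537474, tolerance = 1e-12)
  expect_equal(p$ci_high, 14.239536403464982, tolerance = 1e-12)
  expect_true(all(is.na(prr(contingency_table(5, 10, 0, 40)))))
})

test_that("sign of ROR-1, PRR-1 and ad-bc agree on random positive tables", {
  tabs <- random_tables(2000, seed = 55)
  s_ror <- sign(ror(tabs)$ror - 1)
  s_prr <- sign(prr(tabs)$prr - 1)
  s_det <- sign(tabs$a * tabs$d - tabs$b * tabs$c)
  expect_equal(s_ror, s_det)
  expect_equal(s_prr, s_det)
})

test_that("Yates chi-square equals the library statistic and floors the correction", {
  # |ad - bc| = 0 < n/2: floored to zero
  expect_equal(chisq_yates(contingency_table(10, 10, 10, 10)), 0)
  expect_equal(chisq_yates(contingency_table(20, 10, 5, 40)), 22.5625)
  tabs <- random_tables(500, max_cell = 300, seed = 77)
  got <- chisq_yates(tabs)
  want <- vapply(seq_len(nrow(tabs)), function(i) {
    m <- matrix(c(tabs$a[i], tabs$c[i], tabs$b[i], tabs$d[i]), 2, 2)
    unname(suppressWarnings(stats::chisq.test(m, correct = TRUE)$statistic))
  }, 0)
  expect_equal(got, want, tolerance = 1e-9)
  expect_true(is.na(chisq_yates(contingency_table(0, 0, 5, 40))))
})

test_that("BCPNN matches independent log-space evaluation and is centred on empty data", {
  empty <- bcpnn(contingency_table(0, 0, 0, 0))
  expect_equal(empty$ic, 0)
  got <- bcpnn(contingency_table(20, 10, 5, 40))
  # frozen from independent substitution of the printed expressions
  expect_equal(got$ic, 0.90745122924791366, tolerance = 1e-12)
  expect_equal(got$v_ic, 0.16489222251409921, tolerance = 1e-12)
  expect_equal(got$ic_minus_2sd, 0.095312761955299252, tolerance = 1e-12)
  tabs <- random_tables(500, seed = 42)
  res <- bcpnn(tabs)
  for (i in seq(1, 500, by = 7)) {
    want <- bcpnn_oracle(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(res$ic[i], unname(want["ic"]), tolerance = 1e-12)
    expect_equal(res$v_ic[i], unname(want["v_ic"]), tolerance = 1e-12)
  }
})

test_that("BCPNN shrinks toward, and approaches, the unshrunk ratio at scale", {
  # scale (4,1,1,4): observed/expected = a*n/((a+b)(a+c)) = 1.6 at every k
  ics <- vapply(c(1, 10, 100, 1000), function(k)
    bcpnn(contingency_table(4 * k, k, k, 4 * k))$ic, 0)
  expect_true(all(diff(ics) > 0))
  expect_true(all(ics < log2(1.6)))
  expect_equal(ics[4], log2(1.6), tolerance = 1e-2)
  # shrinkage bound on random tables with a >= 1
  tabs <- random_tables(300, seed = 91)
  res <- bcpnn(tabs)
  unshrunk <- log2(tabs$a * (tabs$a + tabs$b + tabs$c + tabs$d) /
                     ((tabs$a + tabs$b) * (tabs$a + tabs$c)))
  expect_true(all(abs(res$ic) <= abs(unshrunk) + 0.1))
})

test_that("signal flags honour the a>=3 gate and the printed boundary conventions", {
  base <- data.frame(event = "e", case_reports = 2, ror = 50, ror_ci_low = 10,
                     ror_ci_high = 100, prr = 50, prr_ci_low = 10,
                     prr_ci_high = 100, chisq = 100, ic = 3, ic025 = 2,
                     ebgm = 50, ebgm05 = 10)
  gated <- evaluate_signals(base)
  expect_false(any(gated$ror_signal, gated$prr_signal, gated$bcpnn_signal,
                   gated$ebgm_signal, gated$any_of))
  # published SOC-level shape: 69 reports, ROR 6.36 (4.99, 8.11) -> signal
  immune <- base
  immune$case_reports <- 69; immune$ror <- 6.36; immune$ror_ci_low <- 4.99
  expect_true(evaluate_signals(immune)$ror_signal)
  # boundary: ROR >= 2 inclusive but CI low > 1 strict
  edge <- base
  edge$case_reports <- 10; edge$ror <- 2; edge$ror_ci_low <- 1
  expect_false(evaluate_signals(edge)$ror_signal)
  edge$ror_ci_low <- 1.0001
  expect_true(evaluate_signals(edge)$ror_signal)
  # undefined statistics never signal
  und <- base; und$case_reports <- 10; und$ror <- NA; und$ror_ci_low <- NA
  expect_false(evaluate_signals(und)$ror_signal)
})

test_that("ranking is descending, tie-broken by count then label, and stable", {
  res <- data.frame(event = c("b", "a", "c", "d"),
                    case_reports = c(5, 8, 8, 3),
                    ebgm = c(44.27, 227.4, 10, 10))
  ranked <- rank_results(res)
  expect_equal(ranked$event, c("a", "b", "c", "d"))
  set.seed(1)
  shuffled <- res[sample(nrow(res)), ]
  expect_equal(rank_results(shuffled)$event, ranked$event)
  expect_error(rank_results(res, key = "nope"), "ranking key")
  expect_equal(nrow(rank_results(res, top_n = 2)), 2)
})
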