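# ROR / PRR / RR-EBGM / chi-squared point estimates, intervals, screening.
# Frozen expected values come from direct evaluation of the printed
# formulas (hand-calculator arithmetic), independent of the implementation.

test_that("worked examples reproduce the hand-evaluated statistics", {
  t1 <- contingency_table(10, 90, 100, 9900)
  expect_equal(unname(compute_ror(t1)),
               c(11, 5.55951492889, 21.7644887274), tolerance = 1e-9)
  expect_equal(unname(compute_prr(t1)),
               c(10, 5.38215392752, 18.5799219693), tolerance = 1e-9)
  expect_equal(unname(compute_rr_ebgm(t1)),
               c(9.18181818182, 4.64058684147, 18.1670525741),
               tolerance = 1e-9)

  t3 <- contingency_table(3, 97, 100, 9900)
  expect_equal(compute_ror(t3)[["estimate"]], 29700 / 9700,
               tolerance = 1e-12)
  expect_equal(compute_prr(t3)[["estimate"]], 3, tolerance = 1e-12)
  expect_equal(compute_rr_ebgm(t3)[["estimate"]], 30300 / 10300,
               tolerance = 1e-12)
})

test_that("independence tables give exactly 1.0 for all three statistics", {
  ind <- contingency_table(5, 50, 50, 500)  # proportional rows
  expect_identical(compute_ror(ind)[["estimate"]], 1)
  expect_identical(compute_prr(ind)[["estimate"]], 1)
  expect_identical(compute_rr_ebgm(ind)[["estimate"]], 1)
  expect_equal(compute_chi2(ind, yates = FALSE), 0)
})

test_that("chi-squared matches the corrected formula and the generic test", {
  expect_equal(compute_chi2(contingency_table(10, 90, 100, 9900)),
               66.3269408044, tolerance = 1e-9)
  # uncorrected variant against stats::chisq.test on random tables
  set.seed(42)
  for (i in 1:100) {
    x <- rpois(4, lambda = c(20, 200, 200, 5000)) + 1
    ours <- compute_chi2(contingency_table(x[1], x[2], x[3], x[4]),
                         yates = FALSE)
    ref <- suppressWarnings(
      stats::chisq.test(matrix(c(x[1], x[3], x[2], x[4]), 2, 2),
                        correct = FALSE)$statistic)
    expect_equal(ours, unname(ref), tolerance = 1e-9)
  }
})

test_that("zero cells leave statistics undefined unless Haldane-corrected", {
  z <- contingency_table(0, 100, 50, 5000)
  expect_true(all(is.na(compute_ror(z))))
  expect_true(all(is.na(compute_prr(z))))
  expect_true(all(is.na(compute_rr_ebgm(z))))
  h <- compute_ror(z, zero_correction = "haldane")
  expect_false(anyNA(h))
  expect_equal(h[["estimate"]], (0.5 * 5000.5) / (100.5 * 50.5))
  # zero margin kills chi-squared
  expect_true(is.na(compute_chi2(contingency_table(0, 0, 50, 5000))))
})

test_that("ordering ROR > PRR > 1 >= ... and RR <= PRR holds for elevated tables", {
  set.seed(7)
  for (i in 1:200) {
    a <- sample(2:50, 1); b <- sample(10:500, 1)
    c <- sample(10:500, 1); d <- sample(1000:50000, 1)
    if (a * d <= b * c) next
    ror <- compute_ror(contingency_table(a, b, c, d))[["estimate"]]
    prr <- compute_prr(contingency_table(a, b, c, d))[["estimate"]]
    rr <- compute_rr_ebgm(contingency_table(a, b, c, d))[["estimate"]]
    expect_true(ror > prr && prr > 1, info = paste(a, b, c, d))
    expect_lte(rr, prr)
  }
})

test_that("statistics increase strictly in a with the other cells fixed", {
  b <- 200; c <- 100; d <- 20000
  prev <- c(-Inf, -Inf)
  prev_rr <- -Inf
  for (a in c(1, 2, 5, 10, 30, 100, 400)) {
    t <- contingency_table(a, b, c, d)
    cur <- c(compute_ror(t)[["estimate"]], compute_prr(t)[["estimate"]])
    expect_true(all(cur > prev))
    prev <- cur
    # the relative reporting ratio is monotone only while the event stays
    # sparse on both margins (it returns to 1 as a dominates the table)
    if (a <= min(b, c) / 2) {
      rr <- compute_rr_ebgm(t)[["estimate"]]
      expect_gt(rr, prev_rr)
      prev_rr <- rr
    }
  }
})

test_that("screening flags implement the count floor and CI thresholds", {
  crit <- signal_criteria()
  # n = 2 fails the a >= 3 floor no matter how strong the CIs are
  s <- evaluate_signal(contingency_table(2, 8, 10, 99000), crit)
  expect_false(s$flag_ror)
  expect_false(s$flag_prr)
  expect_false(s$is_signal)

  s <- evaluate_signal(contingency_table(10, 90, 100, 9900), crit)
  expect_true(s$flag_ror && s$flag_prr && s$flag_ebgm && s$is_signal)
  expect_equal(s$ebgm05, 4.64058684147, tolerance = 1e-9)
  expect_equal(s$n, 10)

  s <- evaluate_signal(contingency_table(5, 50, 50, 500), crit)
  expect_false(s$flag_ror || s$flag_prr || s$flag_ebgm || s$is_signal)

  # undefined statistics fail their flags
  s <- evaluate_signal(contingency_table(4, 0, 10, 9000), crit)
  expect_false(s$flag_ror)

  # 'any' combination is a disjunction
  crit_any <- signal_criteria(combine = "any", ebgm05_threshold = 100)
  s <- evaluate_signal(contingency_table(10, 90, 100, 9900), crit_any)
  expect_true(s$is_signal)     # ROR/PRR pass even though EBGM cannot
  expect_false(s$flag_ebgm)
})

test_that("CI bounds bracket their point estimates whenever defined", {
  set.seed(11)
  for (i in 1:100) {
    x <- rpois(4, c(5, 100, 80, 8000)) + 1
    t <- contingency_table(x[1], x[2], x[3], x[4])
    for (f in list(compute_ror, compute_prr, compute_rr_ebgm)) {
      v <- f(t)
      expect_true(v[["ci_low"]] <= v[["estimate"]] &&
                    v[["estimate"]] <= v[["ci_high"]])
    }
  }
})

test_that("screening a drug absent from the database yields an empty result", {
  scr <- screen_signals(toy_db(), "ziprasidone")
  expect_equal(nrow(scr$stats), 0)
  expect_equal(nrow(top_signals(scr)), 0)
  expect_output(print(scr), "0 event terms")
})

test_that("screen output is invariant to database row order", {
  gen <- generate_database(small_config(n = 800, seed = 23))
  db <- clean_reports(gen$db)$db
  s1 <- screen_signals(db, "esketamine")$stats

  db2 <- db
  set.seed(5)
  db2$reports <- db2$reports[sample(nrow(db2$reports)), ]
  db2$reactions <- db2$reactions[sample(nrow(db2$reactions)), ]
  db2$drugs <- db2$drugs[sample(nrow(db2$drugs)), ]
  s2 <- screen_signals(db2, "esketamine")$stats
  expect_equal(s1, s2)
})
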