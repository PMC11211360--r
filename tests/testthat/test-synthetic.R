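# Generator determinism, ground-truth bookkeeping, closed-form oracle,
# recovery experiment.

test_that("the same seed reproduces the database exactly", {
  cfg <- small_config(n = 500, seed = 2)
  g1 <- generate_database(cfg)
  g2 <- generate_database(cfg)
  expect_identical(g1$db$reports, g2$db$reports)
  expect_identical(g1$db$drugs, g2$db$drugs)
  expect_identical(g1$db$reactions, g2$db$reactions)
  expect_identical(g1$ledger$duplicate_ids, g2$ledger$duplicate_ids)

  g3 <- generate_database(small_config(n = 500, seed = 3))
  expect_false(identical(g1$db$reports, g3$db$reports))
})

test_that("duplicate injection count is deterministic and ledgered", {
  gen <- generate_database(small_config(n = 1000, seed = 9,
                                        duplicate_rate = 0.05))
  expect_length(gen$ledger$duplicate_ids, 50)
  expect_equal(n_reports(gen$db), 1050)
  # clones share their source's dedup tuple but not its case id
  expect_false(any(gen$ledger$duplicate_ids %in%
                     gen$db$reports$case_id[seq_len(1000)]))
})

test_that("config validation rejects malformed distributions and infeasible implants", {
  expect_error(small_config(demographics = within(
    default_demographics(), sex <- c(female = 0.9, male = 0.3,
                                     unknown = 0.1))),
               "sum to 1")
  bad <- data.frame(ingredient = "esketamine", pt = "Drug ineffective",
                    rate_ratio = 200)
  expect_error(small_config(implanted_signals = bad, cap_rates = FALSE),
               "infeasible")
  cfg <- small_config(implanted_signals = bad)  # capped instead
  gen <- generate_database(small_config(n = 200, seed = 1,
                                        implanted_signals = bad))
  expect_lt(gen$ledger$implanted$effective_rate_ratio, 200)
})

test_that("observed target-event counts fall inside Poisson bounds of the closed form", {
  cfg0 <- generator_config(n_reports = 10000, seed = 0,
                           implanted_signals = no_implant_signals(),
                           duplicate_rate = 0, pre_cutoff_fraction = 0)
  e <- expected_contingency(cfg0, "esketamine", "Panic attack")
  # null pair: expected-cell ROR is exactly 1 by construction
  expect_equal((e$a * e$d) / (e$b * e$c), 1, tolerance = 1e-9)

  obs <- vapply(1:20, function(s) {
    cfg <- generator_config(n_reports = 10000, seed = 1000 + s,
                            implanted_signals = no_implant_signals(),
                            duplicate_rate = 0, pre_cutoff_fraction = 0)
    gen <- generate_database(cfg)
    t <- build_contingency(gen$db, "esketamine", "Panic attack")
    t$a
  }, numeric(1))
  lo <- qpois(0.005, e$a); hi <- qpois(0.995, e$a)
  expect_true(all(obs >= lo & obs <= hi))
  expect_gt(mean(obs >= lo & obs <= hi), 0.9)
})

test_that("implanted pairs reach their configured disproportionality", {
  one <- data.frame(ingredient = "esketamine", pt = "Dissociation",
                    rate_ratio = 20)
  cfg <- generator_config(seed = 8, implanted_signals = one)
  e <- expected_contingency(cfg, "esketamine", "Dissociation")
  or <- (e$a * e$d) / (e$b * e$c)
  expect_gt(or, 19); expect_lt(or, 21)
  expect_error(expected_contingency(cfg, "esketamine", "NotAPT"),
               "unknown PT")
  expect_error(expected_contingency(cfg, "madeupdrug", "Dissociation"),
               "unknown drug")
})

test_that("expected cells satisfy the record-count accounting identity", {
  cfg <- small_config(n = 5000, seed = 44)
  imp <- cfg$implanted_signals
  for (i in seq_len(nrow(imp))) {
    e <- expected_contingency(cfg, imp$ingredient[i], imp$pt[i])
    # every pair partitions the same expected record total
    expect_equal(e$n, expected_contingency(cfg, "fluoxetine", "Nausea")$n,
                 tolerance = 1e-9)
  }
  # and the realised record count matches the expectation closely
  gen <- generate_database(small_config(n = 5000, seed = 44,
                                        duplicate_rate = 0,
                                        pre_cutoff_fraction = 0))
  e <- expected_contingency(cfg, "esketamine", "Dissociation")
  n_rec <- nrow(unique(gen$db$reactions[, c("report_id", "pt")]))
  expect_lt(abs(n_rec - e$n) / e$n, 0.05)
})

test_that("the cleaning pipeline removes exactly the ledger-listed records", {
  cfg <- small_config(n = 2000, seed = 19, duplicate_rate = 0.04,
                      pre_cutoff_fraction = 0.06)
  gen <- generate_database(cfg)
  res <- clean_reports(gen$db)
  removed <- setdiff(gen$db$reports$report_id, res$db$reports$report_id)
  expect_setequal(removed, c(gen$ledger$duplicate_ids,
                             gen$ledger$pre_cutoff_ids))
  expect_setequal(res$cleaning$removed_duplicate_ids,
                  gen$ledger$duplicate_ids)
})

test_that("recovery experiment sees the implants and not the nulls", {
  one <- data.frame(ingredient = "esketamine",
                    pt = c("Dissociation", "Sedation"),
                    rate_ratio = c(20, 1))
  cfg <- generator_config(n_reports = 6000, seed = 300,
                          implanted_signals = one)
  rec <- recovery_experiment(cfg, n_replicates = 20)
  p <- rec$pairs
  expect_equal(p$power[p$pt == "Dissociation"], 1.0)
  # a rate-ratio-1 'implant' is a null pair: consistent estimation
  expect_gt(p$median_ror[p$pt == "Sedation"], 0.8)
  expect_lt(p$median_ror[p$pt == "Sedation"], 1.25)
  expect_lt(rec$null_flag_rate, 0.05)
})
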