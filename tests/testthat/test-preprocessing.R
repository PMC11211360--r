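# Date filtering, target-drug restriction, deduplication.

test_that("date filter is strict: the day before the cutoff goes, the day itself stays", {
  db <- mk_db(list(
    list(id = "A", drug = "esketamine", pts = "Nausea",
         date = as.Date("2019-03-04")),
    list(id = "B", drug = "esketamine", pts = "Nausea",
         date = as.Date("2019-03-05")),
    list(id = "C", drug = "esketamine", pts = "Nausea",
         date = as.Date("2020-01-01"))))
  out <- filter_by_date(db)
  expect_setequal(out$reports$report_id, c("B", "C"))
  # empty database maps to itself
  e <- empty_report_db()
  expect_equal(n_reports(filter_by_date(e)), 0)
})

test_that("undated reports fall back to the first day of the received year", {
  db <- mk_db(list(
    list(id = "A", drug = "esketamine", pts = "Nausea", year = 2018L),
    list(id = "B", drug = "esketamine", pts = "Nausea", year = 2019L),
    list(id = "C", drug = "esketamine", pts = "Nausea", year = 2020L)))
  db$reports$event_date <- as.Date(NA)
  out <- filter_by_date(db)
  # 2019-01-01 is before 2019-03-05, so only the 2020 report survives
  expect_setequal(out$reports$report_id, "C")
})

test_that("target selection requires the drug in the requested role", {
  db <- mk_db(list(
    list(id = "A", drug = "esketamine", role = "concomitant",
         pts = "Nausea"),
    list(id = "B", drug = "esketamine", role = "primary_suspect",
         pts = "Nausea"),
    list(id = "C", drug = "fluoxetine", role = "primary_suspect",
         pts = "Nausea")))
  # B also carries concomitant mentions; membership is enough
  db$drugs <- rbind(db$drugs,
                    mk_drug("B", "quetiapine", "concomitant"),
                    mk_drug("B", "lithium", "concomitant"),
                    mk_drug("B", "valproate", "concomitant"))
  out <- select_target_reports(db, "esketamine")
  expect_equal(out$reports$report_id, "B")
  expect_error(select_target_reports(db, "esketamine", role = "suspect"),
               "configuration error")
})

test_that("brand-name aliases resolve to the target ingredient", {
  db <- mk_db(list(
    list(id = "A", drug = "unspecified", product = "SPRAVATO",
         pts = "Sedation"),
    list(id = "B", drug = "fluoxetine", pts = "Nausea")))
  expect_equal(select_target_reports(db, "esketamine",
                                     aliases = "Spravato")$reports$report_id,
               "A")
  expect_equal(n_reports(select_target_reports(db, "esketamine")), 0)
})

test_that("ground-truth primary-suspect counts are recovered exactly by selection", {
  cfg <- small_config(n = 1500, seed = 7, duplicate_rate = 0,
                      pre_cutoff_fraction = 0)
  gen <- generate_database(cfg)
  sel <- select_target_reports(gen$db, "esketamine")
  expect_equal(n_reports(sel),
               unname(gen$ledger$ps_counts["esketamine"]))
})

test_that("version supersession keeps the highest version of a case", {
  db <- mk_db(list(
    list(id = "X.0", case = "X", version = 0L, drug = "esketamine",
         pts = "Nausea"),
    list(id = "X.1", case = "X", version = 1L, drug = "esketamine",
         pts = c("Nausea", "Sedation"))))
  out <- deduplicate(db)
  expect_equal(out$db$reports$report_id, "X.1")
  expect_equal(out$removed_ids, "X.0")
})

test_that("deduplication is an identity on duplicate-free data and is idempotent", {
  gen <- generate_database(small_config(n = 800, seed = 3,
                                        duplicate_rate = 0))
  d1 <- deduplicate(gen$db)
  expect_equal(length(d1$removed_ids), 0)
  expect_equal(n_reports(d1$db), n_reports(gen$db))

  gen2 <- generate_database(small_config(n = 800, seed = 4,
                                         duplicate_rate = 0.1))
  once <- deduplicate(gen2$db)
  twice <- deduplicate(once$db)
  expect_equal(length(twice$removed_ids), 0)
  expect_identical(once$db$reports, twice$db$reports)
})

test_that("injected duplicates are removed exactly, independent of row order", {
  cfg <- small_config(n = 1000, seed = 11, duplicate_rate = 0.05)
  gen <- generate_database(cfg)
  expect_length(gen$ledger$duplicate_ids, 50)

  out <- deduplicate(gen$db)
  expect_setequal(out$removed_ids, gen$ledger$duplicate_ids)

  # shuffle all tables; the surviving set must not change
  db2 <- gen$db
  set.seed(99)
  db2$reports <- db2$reports[sample(nrow(db2$reports)), ]
  db2$drugs <- db2$drugs[sample(nrow(db2$drugs)), ]
  db2$reactions <- db2$reactions[sample(nrow(db2$reactions)), ]
  out2 <- deduplicate(db2)
  expect_setequal(out2$db$reports$report_id, out$db$reports$report_id)
})

test_that("version-only mode skips the demographic-tuple stage", {
  cfg <- small_config(n = 600, seed = 12, duplicate_rate = 0.05)
  gen <- generate_database(cfg)
  res <- clean_reports(gen$db, dedup_mode = "version")
  # clones carry fresh case ids, so version-only dedup removes none of them
  expect_equal(res$cleaning$n_duplicates_removed, 0)
  res_full <- clean_reports(gen$db, dedup_mode = "full")
  expect_equal(res_full$cleaning$n_duplicates_removed,
               length(gen$ledger$duplicate_ids))
})

test_that("date filter and target selection commute", {
  gen <- generate_database(small_config(n = 1200, seed = 21))
  a <- select_target_reports(filter_by_date(gen$db), "esketamine")
  b <- filter_by_date(select_target_reports(gen$db, "esketamine"))
  expect_setequal(a$reports$report_id, b$reports$report_id)
})

test_that("cleaning report satisfies its accounting identity", {
  gen <- generate_database(small_config(n = 1000, seed = 31))
  res <- clean_reports(gen$db)
  cl <- res$cleaning
  expect_equal(cl$n_output, cl$n_after_date_filter - cl$n_duplicates_removed)
  expect_lte(cl$n_output, cl$n_input)
  # reports with no coded reactions are dropped and counted
  db <- mk_db(list(
    list(id = "A", drug = "esketamine", pts = "Nausea"),
    list(id = "B", drug = "esketamine", pts = "Sedation"),
    list(id = "C", drug = "fluoxetine", pts = "Headache")))
  db$reactions <- db$reactions[db$reactions$report_id != "B", ]
  res2 <- clean_reports(db)
  expect_equal(res2$cleaning$n_empty_removed, 1)
  expect_setequal(res2$db$reports$report_id, c("A", "C"))
})
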