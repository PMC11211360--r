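# Synthetic spontaneous-report generator with a ground-truth ledger.
#
# Reports are drawn independently. Each report samples drug presence from
# per-drug marginals (redrawn until at least one drug is present, so the
# realised distribution is the independence model conditioned on >= 1
# drug), assigns the primary-suspect role per drug, then samples each
# preferred term from its marginal -- multiplied by the implanted rate
# ratio (capped at 1) when an implanted (drug, PT) pair has its drug
# present as primary suspect -- again redrawn until >= 1 reaction.
# Demographics are independent categoricals. A configured fraction of
# reports is dated before the cleaning cutoff, and duplicate contamination
# is injected by cloning post-cutoff reports under fresh case identifiers
# with identical deduplication tuples. Everything is a pure function of
# the config, including its seed.

#' Default synthetic drug catalog
#'
#' Esketamine as the target compound plus nine background antidepressant /
#' psychotropic ingredients, with per-report marginal presence
#' probabilities and the probability that a present drug is coded primary
#' suspect.
#'
#' @return data.frame with columns `ingredient`, `p_marginal`, `p_primary`.
#' @export
default_drug_catalog <- function() {
  data.frame(
    ingredient = c("esketamine", "fluoxetine", "sertraline", "quetiapine",
                   "venlafaxine", "bupropion", "aripiprazole", "lithium",
                   "lamotrigine", "duloxetine"),
    p_marginal = c(0.028, 0.25, 0.25, 0.20, 0.20, 0.20, 0.15, 0.15, 0.15,
                   0.20),
    p_primary = c(0.80, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50,
                  0.50),
    stringsAsFactors = FALSE)
}

#' Default synthetic event catalog
#'
#' Preferred terms drawn from the bundled PT->SOC mapping with marginal
#' per-report inclusion probabilities loosely shaped like a psychiatric
#' spontaneous-report database (frequent nonspecific terms, a tail of rare
#' ones). The five dissociation/sedation-spectrum terms carry a low base
#' rate (0.005) so that implanting a rate ratio on them stays far from the
#' probability cap.
#'
#' @return data.frame with columns `pt`, `soc`, `p_marginal`.
#' @export
default_event_catalog <- function() {
  pts <- c(
    "Dissociation" = 0.005, "Sedation" = 0.005,
    "Dissociative disorder" = 0.005, "Feeling drunk" = 0.005,
    "Euphoric mood" = 0.005,
    "Drug ineffective" = 0.08, "Nausea" = 0.07, "Headache" = 0.06,
    "Dizziness" = 0.06, "Fatigue" = 0.05, "Anxiety" = 0.05,
    "Depression" = 0.05, "Insomnia" = 0.04, "Vomiting" = 0.04,
    "Somnolence" = 0.03, "Rash" = 0.03, "Myalgia" = 0.03,
    "Hypertension" = 0.03, "Blood pressure increased" = 0.03,
    "Nasopharyngitis" = 0.03, "Feeling abnormal" = 0.03,
    "Suicidal ideation" = 0.02, "Vision blurred" = 0.02,
    "Tachycardia" = 0.02, "Vertigo" = 0.02, "Throat irritation" = 0.02,
    "Weight decreased" = 0.02, "Dysgeusia" = 0.02, "Fall" = 0.02,
    "Decreased appetite" = 0.03, "Hypersensitivity" = 0.01,
    "Pollakiuria" = 0.01, "Panic attack" = 0.01, "Hallucination" = 0.01,
    "Nasal discomfort" = 0.01, "Suicide attempt" = 0.01,
    "Product use issue" = 0.01, "Product quality issue" = 0.01,
    "Liver disorder" = 0.005, "Hypothyroidism" = 0.005,
    "Erectile dysfunction" = 0.005, "Neoplasm" = 0.005,
    "Hospitalisation" = 0.005, "Alcohol abuse" = 0.005,
    "Loss of employment" = 0.003, "Cystitis interstitial" = 0.003,
    "Hyperacusis" = 0.003, "Abortion spontaneous" = 0.002,
    "Abdominoplasty" = 0.002, "Tachyphylaxis" = 0.002)
  data.frame(pt = names(pts), soc = map_pt_to_soc(names(pts)),
             p_marginal = unname(pts), stringsAsFactors = FALSE)
}

#' Default demographic distributions
#'
#' Categorical distributions for sex, age group, country, reporter type,
#' received year and seriousness, shaped like the published descriptive
#' margins of the esketamine nasal spray safety profile (female-dominated,
#' mostly US, mostly healthcare-professional reports, rising yearly
#' volume, ~60% serious).
#'
#' @return named list of named probability vectors.
#' @export
default_demographics <- function() {
  list(
    sex = c(female = 0.530, male = 0.296, unknown = 0.174),
    age_group = c("<18" = 0.008, "18-64" = 0.493, ">=65" = 0.077,
                  unknown = 0.422),
    country = c("US" = 0.798, "FR" = 0.035, "BR" = 0.020, "DE" = 0.014,
                "ES" = 0.014, Other = 0.119),
    reporter_type = c(healthcare_professional = 0.788, consumer = 0.211,
                      unknown = 0.001),
    year = c("2019" = 0.098, "2020" = 0.157, "2021" = 0.190,
             "2022" = 0.224, "2023" = 0.331),
    seriousness = c(serious = 0.604, non_serious = 0.396))
}

#' Configure the synthetic report generator
#'
#' Validates and freezes every parameter of the generative model. The
#' defaults emulate a five-year, esketamine-centred slice of a
#' spontaneous-report database: ~2% of reports carry the target drug as
#' primary suspect, five dissociation/sedation-spectrum terms are
#' implanted at rate ratio 20 (expected target-event counts around 30-40
#' per 10,000 reports), 5% duplicate contamination and 5% pre-cutoff
#' reports.
#'
#' @param n_reports number of original (pre-duplicate) reports.
#' @param drug_catalog data.frame (`ingredient`, `p_marginal`,
#'   `p_primary`).
#' @param event_catalog data.frame (`pt`, `soc`, `p_marginal`).
#' @param implanted_signals data.frame (`ingredient`, `pt`, `rate_ratio`)
#'   of ground-truth associations; may have zero rows.
#' @param duplicate_rate fraction in [0, 1): `round(rate * n_reports)`
#'   clones are injected.
#' @param demographics named list of probability vectors as in
#'   [default_demographics()]; each must sum to 1.
#' @param pre_cutoff_fraction fraction of reports dated before
#'   2019-03-05.
#' @param seed integer seed; all randomness derives from it.
#' @param cap_rates if `TRUE` (default) implanted inclusion probabilities
#'   are capped at 1 and the ledger records the effective (post-cap) rate
#'   ratio; if `FALSE`, a configuration whose `rate_ratio * p_marginal`
#'   exceeds 1 is a validation error.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_reports = 10000,
                             drug_catalog = default_drug_catalog(),
                             event_catalog = default_event_catalog(),
                             implanted_signals = data.frame(
                               ingredient = "esketamine",
                               pt = c("Dissociation", "Sedation",
                                      "Dissociative disorder",
                                      "Feeling drunk", "Euphoric mood"),
                               rate_ratio = 20,
                               stringsAsFactors = FALSE),
                             duplicate_rate = 0.05,
                             demographics = default_demographics(),
                             pre_cutoff_fraction = 0.05,
                             seed = 20190305,
                             cap_rates = TRUE) {
  stopifnot(n_reports >= 1,
            all(c("ingredient", "p_marginal", "p_primary") %in%
                  names(drug_catalog)),
            all(c("pt", "soc", "p_marginal") %in% names(event_catalog)),
            duplicate_rate >= 0, duplicate_rate < 1,
            pre_cutoff_fraction >= 0, pre_cutoff_fraction < 1)
  if (any(drug_catalog$p_marginal <= 0 | drug_catalog$p_marginal >= 1) ||
      any(drug_catalog$p_primary <= 0 | drug_catalog$p_primary > 1))
    stop("drug catalog probabilities must lie in (0, 1)")
  if (any(event_catalog$p_marginal <= 0 | event_catalog$p_marginal >= 1))
    stop("event catalog probabilities must lie in (0, 1)")
  if (anyDuplicated(drug_catalog$ingredient) ||
      anyDuplicated(event_catalog$pt))
    stop("catalog entries must be unique")
  for (nm in names(demographics)) {
    p <- demographics[[nm]]
    if (abs(sum(p) - 1) > 1e-8)
      stop("demographic distribution ", shQuote(nm), " must sum to 1")
    if (any(p < 0)) stop("demographic probabilities must be non-negative")
  }
  if (nrow(implanted_signals)) {
    stopifnot(all(c("ingredient", "pt", "rate_ratio") %in%
                    names(implanted_signals)))
    if (any(implanted_signals$rate_ratio <= 0))
      stop("rate ratios must be > 0")
    if (!all(implanted_signals$ingredient %in% drug_catalog$ingredient))
      stop("implanted ingredient not in drug catalog")
    if (!all(implanted_signals$pt %in% event_catalog$pt))
      stop("implanted PT not in event catalog")
    q <- event_catalog$p_marginal[match(implanted_signals$pt,
                                        event_catalog$pt)]
    over <- implanted_signals$rate_ratio * q > 1
    if (any(over) && !cap_rates)
      stop("infeasible config: rate_ratio * p_marginal > 1 for pair(s) ",
           paste(implanted_signals$ingredient[over],
                 implanted_signals$pt[over], sep = ":", collapse = ", "))
  }
  structure(list(n_reports = as.integer(n_reports),
                 drug_catalog = drug_catalog,
                 event_catalog = event_catalog,
                 implanted_signals = implanted_signals,
                 duplicate_rate = duplicate_rate,
                 demographics = demographics,
                 pre_cutoff_fraction = pre_cutoff_fraction,
                 seed = as.integer(seed), cap_rates = cap_rates,
                 cutoff_date = as.Date("2019-03-05")),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> ", x$n_reports, " reports, ",
      nrow(x$drug_catalog), " drugs, ", nrow(x$event_catalog), " PTs, ",
      nrow(x$implanted_signals), " implanted pairs; dup rate ",
      x$duplicate_rate, ", pre-cutoff ", x$pre_cutoff_fraction,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

OUTCOME_MIX <- c(hospitalization = 0.50, other_serious = 0.30,
                 life_threatening = 0.10, death = 0.06, disability = 0.035,
                 congenital_anomaly = 0.005)

# per-report effective PT inclusion probabilities, given which drugs are PS
effective_event_probs <- function(config, ps_matrix) {
  n <- nrow(ps_matrix)
  q <- matrix(config$event_catalog$p_marginal, n,
              nrow(config$event_catalog), byrow = TRUE)
  imp <- config$implanted_signals
  if (nrow(imp)) {
    for (i in seq_len(nrow(imp))) {
      g <- match(imp$ingredient[i], config$drug_catalog$ingredient)
      p <- match(imp$pt[i], config$event_catalog$pt)
      rows <- ps_matrix[, g]
      q[rows, p] <- q[rows, p] * imp$rate_ratio[i]
    }
    q <- pmin(q, 1)
  }
  q
}

#' Generate a synthetic report database with ground truth
#'
#' Draws a full FAERS-like database from a [generator_config()] and
#' returns it together with a ledger recording everything a validation
#' needs: the injected duplicate report ids, the pre-cutoff report ids,
#' the implanted pairs with their effective (post-cap) rate ratios,
#' per-ingredient primary-suspect report counts and closed-form expected
#' contingency cells for every implanted pair. Event-date collisions in
#' the deduplication tuple are resolved by deterministic one-day shifts
#' before duplicates are injected, so running [clean_reports()] on the
#' output removes exactly the ledger-listed records.
#'
#' @param config a `generator_config`.
#' @return list with elements `db` (a `report_db`) and `ledger` (class
#'   `ground_truth_ledger`).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_reports
  dc <- config$drug_catalog
  ec <- config$event_catalog
  n_drugs <- nrow(dc)
  n_pts <- nrow(ec)

  # drug presence, conditioned on >= 1 by redraw
  pres <- matrix(stats::runif(n * n_drugs), n, n_drugs) <
    matrix(dc$p_marginal, n, n_drugs, byrow = TRUE)
  empty <- which(rowSums(pres) == 0L)
  while (length(empty)) {
    pres[empty, ] <- matrix(stats::runif(length(empty) * n_drugs),
                            length(empty), n_drugs) <
      matrix(dc$p_marginal, length(empty), n_drugs, byrow = TRUE)
    empty <- empty[rowSums(pres[empty, , drop = FALSE]) == 0L]
  }

  # roles: primary suspect with p_primary given presence
  ps <- pres & (matrix(stats::runif(n * n_drugs), n, n_drugs) <
                  matrix(dc$p_primary, n, n_drugs, byrow = TRUE))
  role_u <- matrix(stats::runif(n * n_drugs), n, n_drugs)

  # reactions, conditioned on >= 1 by redraw (probabilities fixed first)
  q <- effective_event_probs(config, ps)
  reac <- matrix(stats::runif(n * n_pts), n, n_pts) < q
  empty <- which(rowSums(reac) == 0L)
  while (length(empty)) {
    reac[empty, ] <- matrix(stats::runif(length(empty) * n_pts),
                            length(empty), n_pts) <
      q[empty, , drop = FALSE]
    empty <- empty[rowSums(reac[empty, , drop = FALSE]) == 0L]
  }

  dg <- config$demographics
  sex <- sample_cat(n, dg$sex)
  age_group <- sample_cat(n, dg$age_group)
  country <- sample_cat(n, dg$country)
  reporter <- sample_cat(n, dg$reporter_type)
  year <- as.integer(sample_cat(n, dg$year))
  seriousness <- sample_cat(n, dg$seriousness)
  outcomes <- ifelse(seriousness == "serious",
                     sample_cat(n, OUTCOME_MIX), "")
  weight <- round(stats::rnorm(n, 75, 15), 1)
  weight[weight < 30] <- NA_real_
  weight[stats::runif(n) < 0.4] <- NA_real_

  # dates: a deterministic count of pre-cutoff reports, the rest placed
  # on or after the cutoff within their received year
  n_pre <- round(config$pre_cutoff_fraction * n)
  pre_idx <- if (n_pre > 0) sort(sample.int(n, n_pre)) else integer()
  cutoff <- config$cutoff_date
  pre_window <- as.integer(cutoff - as.Date("2019-01-01"))  # 63 days
  event_date <- rep(cutoff, n)
  is_pre <- seq_len(n) %in% pre_idx
  year[is_pre] <- 2019L
  event_date[is_pre] <- as.Date("2019-01-01") +
    (sample.int(pre_window, sum(is_pre), replace = TRUE) - 1L)
  post <- !is_pre
  yr_start <- as.Date(paste0(year, "-01-01"))
  yr_len <- as.integer(as.Date(paste0(year, "-12-31")) - yr_start) + 1L
  off <- floor(stats::runif(n) * yr_len)
  d <- yr_start + off
  d[post & d < cutoff] <- cutoff + off[post & d < cutoff] %% 200L
  event_date[post] <- d[post]

  report_id <- sprintf("R%07d", seq_len(n))
  case_id <- sprintf("C%07d", seq_len(n))

  reports <- data.frame(report_id = report_id, case_id = case_id,
                        version = 0L, sex = sex, age_group = age_group,
                        weight_kg = weight, country = country,
                        reporter_type = reporter, received_year = year,
                        event_date = event_date,
                        seriousness = seriousness,
                        serious_outcomes = outcomes,
                        stringsAsFactors = FALSE)

  # long drug table
  pres_idx <- which(pres, arr.ind = TRUE)
  is_ps <- ps[pres_idx]
  u <- role_u[pres_idx]
  role <- ifelse(is_ps, "primary_suspect",
                 ifelse(u < 0.6, "concomitant",
                        ifelse(u < 0.9, "secondary_suspect", "interacting")))
  drugs <- data.frame(report_id = report_id[pres_idx[, 1]],
                      active_ingredient = dc$ingredient[pres_idx[, 2]],
                      product_name = NA_character_, role = role,
                      reason_for_use = NA_character_,
                      stringsAsFactors = FALSE)

  reac_idx <- which(reac, arr.ind = TRUE)
  reactions <- data.frame(report_id = report_id[reac_idx[, 1]],
                          pt = ec$pt[reac_idx[, 2]],
                          soc = ec$soc[reac_idx[, 2]],
                          stringsAsFactors = FALSE)
  ord <- order(reactions$report_id, reactions$pt)
  reactions <- reactions[ord, , drop = FALSE]

  db <- report_db(reports, drugs, reactions,
                  provenance = paste0("synthetic seed ", config$seed),
                  validate = FALSE)

  # make dedup tuples unique among originals (deterministic day shifts),
  # so injected clones are the only stage-2 duplicates
  db <- disambiguate_dedup_tuples(db, cutoff)

  # duplicate injection: clone post-cutoff originals under new case ids
  n_dup <- round(config$duplicate_rate * n)
  dup_ids <- character()
  if (n_dup > 0) {
    post_ids <- db$reports$report_id[!(seq_len(n) %in% pre_idx)]
    if (n_dup > length(post_ids))
      stop("duplicate_rate too high for the number of post-cutoff reports")
    src <- sort(sample(post_ids, n_dup))
    clone_rep <- db$reports[match(src, db$reports$report_id), , drop = FALSE]
    clone_rep$report_id <- sprintf("R%07d", n + seq_len(n_dup))
    clone_rep$case_id <- sprintf("ZD%06d", seq_len(n_dup))
    remap <- function(tbl) {
      sel <- tbl[tbl$report_id %in% src, , drop = FALSE]
      sel$report_id <- clone_rep$report_id[match(sel$report_id, src)]
      sel
    }
    db$reports <- rbind(db$reports, clone_rep)
    db$drugs <- rbind(db$drugs, remap(db$drugs))
    db$reactions <- rbind(db$reactions, remap(db$reactions))
    rownames(db$reports) <- rownames(db$drugs) <-
      rownames(db$reactions) <- NULL
    dup_ids <- clone_rep$report_id
  }
  validate_report_db(db)

  ps_counts <- colSums(ps)
  names(ps_counts) <- dc$ingredient

  imp <- config$implanted_signals
  eff_rr <- if (nrow(imp)) {
    qbase <- ec$p_marginal[match(imp$pt, ec$pt)]
    pmin(imp$rate_ratio, 1 / qbase)
  } else numeric()
  expected <- if (nrow(imp)) {
    cells <- lapply(seq_len(nrow(imp)), function(i)
      expected_contingency(config, imp$ingredient[i], imp$pt[i]))
    data.frame(ingredient = imp$ingredient, pt = imp$pt,
               a = vapply(cells, function(t) t$a, numeric(1)),
               b = vapply(cells, function(t) t$b, numeric(1)),
               c = vapply(cells, function(t) t$c, numeric(1)),
               d = vapply(cells, function(t) t$d, numeric(1)),
               stringsAsFactors = FALSE)
  } else data.frame(ingredient = character(), pt = character(),
                    a = numeric(), b = numeric(), c = numeric(),
                    d = numeric())

  ledger <- structure(list(
    duplicate_ids = dup_ids,
    pre_cutoff_ids = report_id[pre_idx],
    implanted = cbind(imp,
                      effective_rate_ratio = eff_rr)[seq_len(nrow(imp)), ,
                                                     drop = FALSE],
    expected_cells = expected,
    ps_counts = ps_counts,
    n_original = n,
    config = config), class = "ground_truth_ledger")

  list(db = db, ledger = ledger)
}

#' @export
print.ground_truth_ledger <- function(x, ...) {
  cat("<ground_truth_ledger> ", x$n_original, " original reports, ",
      length(x$duplicate_ids), " injected duplicates, ",
      length(x$pre_cutoff_ids), " pre-cutoff reports, ",
      nrow(x$implanted), " implanted pairs\n", sep = "")
  invisible(x)
}

# shift event dates of tuple-colliding originals by whole days until every
# dedup key is unique; pre-cutoff reports stay strictly before the cutoff
disambiguate_dedup_tuples <- function(db, cutoff) {
  for (pass in 1:400) {
    key <- dedup_key(db)
    dup <- duplicated(key)
    if (!any(dup)) return(db)
    i <- which(dup)
    d <- db$reports$event_date[i]
    pre <- !is.na(d) & d < cutoff
    d[!pre] <- d[!pre] + 1L
    wrap <- pre & (d + 1L >= cutoff)
    d[pre & !wrap] <- d[pre & !wrap] + 1L
    d[wrap] <- as.Date("2019-01-01") + (pass %% 60)
    db$reports$event_date[i] <- d
  }
  stop("could not disambiguate deduplication tuples in 400 passes")
}

#' Closed-form expected contingency cells under the generative model
#'
#' Computes the expected a/b/c/d cells (event-record unit, PT level) for
#' one drug-event pair under a [generator_config()], before duplicate
#' injection and date filtering, by enumerating the primary-suspect status
#' of every drug carrying an implanted signal and applying the exact
#' conditional-on-nonempty inclusion probabilities the sampler uses. This
#' is the oracle that parameter-recovery tests compare estimates against.
#'
#' @param config a `generator_config`.
#' @param drug,pt the pair (both must be in the catalogs).
#' @param post_cleaning if `TRUE`, scale by the post-cutoff fraction to
#'   approximate cells after date filtering and exact dedup.
#' @return a [contingency_table()] of expected (non-integer) counts.
#' @export
expected_contingency <- function(config, drug, pt, post_cleaning = FALSE) {
  dc <- config$drug_catalog
  ec <- config$event_catalog
  gi <- match(drug, dc$ingredient)
  pi <- match(pt, ec$pt)
  if (is.na(gi)) stop("unknown drug: ", drug)
  if (is.na(pi)) stop("unknown PT: ", pt)

  imp <- config$implanted_signals
  enum_drugs <- union(drug, unique(imp$ingredient))
  k <- length(enum_drugs)
  s <- dc$p_marginal[match(enum_drugs, dc$ingredient)] *
    dc$p_primary[match(enum_drugs, dc$ingredient)]
  p0 <- prod(1 - dc$p_marginal)  # all drugs absent
  norm <- 1 - p0

  a <- b <- c <- d <- 0
  for (mask in 0:(2^k - 1)) {
    is_ps <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    p_pat <- prod(ifelse(is_ps, s, 1 - s))
    if (!any(is_ps)) p_pat <- p_pat - p0  # exclude the no-drug event
    p_pat <- p_pat / norm
    if (p_pat <= 0) next

    qe <- ec$p_marginal
    if (nrow(imp)) for (j in seq_len(nrow(imp))) {
      if (is_ps[match(imp$ingredient[j], enum_drugs)]) {
        pj <- match(imp$pt[j], ec$pt)
        qe[pj] <- qe[pj] * imp$rate_ratio[j]
      }
    }
    qe <- pmin(qe, 1)
    denom <- 1 - prod(1 - qe)
    e_evt <- qe[pi] / denom            # P(pt present | >= 1 reaction)
    e_tot <- sum(qe) / denom           # E[# reaction records | >= 1]

    target_row <- is_ps[match(drug, enum_drugs)]
    w <- config$n_reports * p_pat
    if (target_row) {
      a <- a + w * e_evt
      b <- b + w * (e_tot - e_evt)
    } else {
      c <- c + w * e_evt
      d <- d + w * (e_tot - e_evt)
    }
  }
  if (post_cleaning) {
    f <- 1 - config$pre_cutoff_fraction
    a <- a * f; b <- b * f; c <- c * f; d <- d * f
  }
  contingency_table(a, b, c, d, term = pt, level = "PT")
}

#' Estimator recovery experiment on synthetic databases
#'
#' Generates `n_replicates` databases from the config (seeds
#' `config$seed + 1, ..., + n_replicates`), runs the full pipeline
#' (clean, tabulate, screen) on each, and summarises estimator behaviour:
#' per implanted pair the median ROR estimate, the coverage of the 95% CI
#' over the generative odds ratio (computed from the closed-form expected
#' cells) and the detection power under the given criteria; plus the
#' false-flag rate over all null terms.
#'
#' @param config a `generator_config`.
#' @param n_replicates number of simulated databases (>= 2).
#' @param criteria a [signal_criteria()].
#' @return object of class `recovery_summary`: list with `pairs` (one row
#'   per implanted pair: `median_ror`, `ci_coverage`, `power`),
#'   `null_flag_rate`, and `n_replicates`.
#' @export
recovery_experiment <- function(config, n_replicates = 20,
                                criteria = signal_criteria()) {
  stopifnot(n_replicates >= 2)
  imp <- config$implanted_signals
  targets <- unique(imp$ingredient)
  gen_or <- vapply(seq_len(nrow(imp)), function(i) {
    t <- expected_contingency(config, imp$ingredient[i], imp$pt[i])
    (t$a * t$d) / (t$b * t$c)
  }, numeric(1))

  ror_est <- matrix(NA_real_, n_replicates, nrow(imp))
  covered <- hit <- matrix(FALSE, n_replicates, nrow(imp))
  null_flags <- null_total <- 0

  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    gen <- generate_database(cfg)
    db <- clean_reports(gen$db)$db
    for (g in targets) {
      scr <- screen_signals(db, g, level = "PT", criteria = criteria)
      s <- scr$stats
      rows <- which(imp$ingredient == g)
      idx <- match(imp$pt[rows], s$term)
      ror_est[r, rows] <- s$ror[idx]
      covered[r, rows] <- !is.na(idx) & !is.na(s$ror_low[idx]) &
        s$ror_low[idx] <= gen_or[rows] & gen_or[rows] <= s$ror_high[idx]
      hit[r, rows] <- !is.na(idx) & s$is_signal[idx]
      null_terms <- setdiff(s$term, imp$pt[imp$ingredient == g])
      null_flags <- null_flags + sum(s$is_signal[s$term %in% null_terms])
      null_total <- null_total + length(null_terms)
    }
  }
  pairs <- data.frame(ingredient = imp$ingredient, pt = imp$pt,
                      rate_ratio = imp$rate_ratio,
                      generative_or = gen_or,
                      median_ror = apply(ror_est, 2, stats::median,
                                         na.rm = TRUE),
                      ci_coverage = colMeans(covered),
                      power = colMeans(hit),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 null_flag_rate = if (null_total) null_flags / null_total
                                  else NA_real_,
                 n_replicates = n_replicates),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("<recovery_summary> ", x$n_replicates, " replicates; null flag rate ",
      format(x$null_flag_rate, digits = 3), "\n", sep = "")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
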