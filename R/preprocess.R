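# Record cleaning: date/informativeness filtering, target-drug restriction
# by suspect role, and two-stage duplicate removal.

subset_db <- function(db, keep_ids) {
  db$reports <- db$reports[db$reports$report_id %in% keep_ids, , drop = FALSE]
  db$drugs <- db$drugs[db$drugs$report_id %in% keep_ids, , drop = FALSE]
  db$reactions <- db$reactions[db$reactions$report_id %in% keep_ids, ,
                               drop = FALSE]
  rownames(db$reports) <- rownames(db$drugs) <- rownames(db$reactions) <- NULL
  db
}

report_date <- function(reports) {
  # fallback for undated reports: first day of the received year
  d <- reports$event_date
  fb <- is.na(d) & !is.na(reports$received_year)
  if (any(fb))
    d[fb] <- as.Date(paste0(reports$received_year[fb], "-01-01"))
  d
}

#' Remove reports dated before a cutoff
#'
#' Drops reports whose event date (falling back to the first day of the
#' received year when the event date is missing) is strictly earlier than
#' the cutoff. The default cutoff is the 5 March 2019 marketing-approval
#' date used when screening esketamine nasal spray, so pre-marketing noise
#' is excluded; reports dated exactly on the cutoff are kept. Reports with
#' neither date nor year cannot be placed in time and are kept.
#'
#' @param db a `report_db`.
#' @param cutoff_date a `Date` (or string coercible to one).
#' @return the filtered `report_db`.
#' @export
filter_by_date <- function(db, cutoff_date = as.Date("2019-03-05")) {
  cutoff_date <- as.Date(cutoff_date)
  if (!nrow(db$reports)) return(db)
  d <- report_date(db$reports)
  drop <- !is.na(d) & d < cutoff_date
  subset_db(db, db$reports$report_id[!drop])
}

#' Restrict to reports naming a target drug in a given role
#'
#' Keeps reports holding at least one drug mention whose normalised active
#' ingredient or product name matches the target (the normalisation strips
#' case, whitespace and punctuation, so `"Esketamine"` matches
#' `"ESKETAMINE"`), in the requested role. Restricting to
#' `role = "primary_suspect"` reproduces the usual target-drug definition
#' for disproportionality analyses.
#'
#' @param db a `report_db`.
#' @param ingredient target active ingredient.
#' @param role drug role that qualifies a report (default primary suspect).
#' @param aliases additional names resolving to the target (e.g. the brand
#'   name `"Spravato"` for esketamine nasal spray).
#' @return the filtered `report_db`.
#' @export
select_target_reports <- function(db, ingredient, role = "primary_suspect",
                                  aliases = character()) {
  if (!role %in% ROLE_LEVELS)
    stop("configuration error: unknown drug role ", shQuote(role))
  targets <- normalize_drug_name(c(ingredient, aliases))
  d <- db$drugs
  hit <- d$role == role &
    (normalize_drug_name(d$active_ingredient) %in% targets |
       (!is.na(d$product_name) &
          normalize_drug_name(d$product_name) %in% targets))
  subset_db(db, unique(d$report_id[hit]))
}

is_target_report <- function(db, ingredient, role = "primary_suspect",
                             aliases = character()) {
  sel <- select_target_reports(db, ingredient, role, aliases)
  db$reports$report_id %in% sel$reports$report_id
}

dedup_key <- function(db) {
  r <- db$reports
  pt_key <- rep("", nrow(r))
  if (nrow(db$reactions)) {
    sp <- split(db$reactions$pt, db$reactions$report_id)
    keys <- vapply(sp, function(v) paste(sort(v), collapse = "|"),
                   character(1))
    idx <- match(r$report_id, names(keys))
    pt_key[!is.na(idx)] <- keys[idx[!is.na(idx)]]
  }
  paste(r$sex, r$age_group, r$country,
        ifelse(is.na(r$event_date), "NA", format(r$event_date, "%Y-%m-%d")),
        pt_key, r$seriousness, sep = "\r")
}

#' Remove duplicate case reports
#'
#' Two-stage deduplication in the usual FAERS manner. Stage one keeps only
#' the highest version of each `case_id` (later versions supersede earlier
#' submissions of the same case). Stage two (`mode = "full"`, the default)
#' additionally collapses distinct case identifiers that are identical on
#' the tuple (sex, age group, country, event date, sorted PT multiset,
#' seriousness) -- the fingerprint of one clinical episode submitted twice
#' -- keeping the most recently received report. All ties break
#' deterministically: equal versions or equal receipt years resolve to the
#' lexicographically smallest `case_id` (then `report_id`), so the result
#' does not depend on input row order.
#'
#' @param db a `report_db`.
#' @param mode `"full"` (both stages) or `"version"` (stage one only).
#' @return list with elements `db` (the deduplicated database) and
#'   `removed_ids` (the `report_id`s that were dropped).
#' @export
deduplicate <- function(db, mode = c("full", "version")) {
  mode <- match.arg(mode)
  r <- db$reports
  if (!nrow(r)) return(list(db = db, removed_ids = character()))

  # stage 1: highest version per case_id, ties to smallest report_id
  ord <- order(r$case_id, -r$version, r$report_id)
  keep1 <- !duplicated(r$case_id[ord])
  keep_ids <- r$report_id[ord][keep1]
  db1 <- subset_db(db, keep_ids)

  if (mode == "full" && nrow(db1$reports) > 1) {
    key <- dedup_key(db1)
    r1 <- db1$reports
    yr <- r1$received_year
    yr[is.na(yr)] <- -Inf
    ord2 <- order(key, -yr, r1$case_id, r1$report_id)
    keep2 <- !duplicated(key[ord2])
    keep_ids <- sort(r1$report_id[ord2][keep2])
    db1 <- subset_db(db1, keep_ids)
  }
  removed <- setdiff(r$report_id, db1$reports$report_id)
  list(db = db1, removed_ids = removed)
}

#' Clean a report database
#'
#' The full cleaning stage: (i) remove reports dated before the cutoff and
#' reports with no coded reactions (both are low-informative records that
#' cannot enter the analysis), then (ii) deduplicate. Returns the cleaned
#' database together with a `cleaning_report` audit trail whose counts
#' satisfy `n_output = n_after_date_filter - n_duplicates_removed`.
#'
#' @param db a `report_db`.
#' @param cutoff_date strict lower date bound, as in [filter_by_date()].
#' @param dedup_mode `"full"` or `"version"`, as in [deduplicate()].
#' @return list with elements `db` and `cleaning` (class `cleaning_report`:
#'   `n_input`, `n_after_date_filter`, `n_empty_removed`,
#'   `n_duplicates_removed`, `n_output`).
#' @export
clean_reports <- function(db, cutoff_date = as.Date("2019-03-05"),
                          dedup_mode = c("full", "version")) {
  dedup_mode <- match.arg(dedup_mode)
  n_input <- nrow(db$reports)
  db1 <- filter_by_date(db, cutoff_date)
  n_after_date <- nrow(db1$reports)
  with_reac <- unique(db1$reactions$report_id)
  db1 <- subset_db(db1, intersect(db1$reports$report_id, with_reac))
  n_empty <- n_after_date - nrow(db1$reports)
  n_after_filter <- nrow(db1$reports)
  dd <- deduplicate(db1, mode = dedup_mode)
  cleaning <- structure(list(n_input = n_input,
                             n_after_date_filter = n_after_filter,
                             n_empty_removed = n_empty,
                             n_duplicates_removed = length(dd$removed_ids),
                             n_output = nrow(dd$db$reports),
                             removed_duplicate_ids = dd$removed_ids),
                        class = "cleaning_report")
  list(db = dd$db, cleaning = cleaning)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n",
      "  input reports:        ", x$n_input, "\n",
      "  after date/empty cut: ", x$n_after_date_filter,
      " (", x$n_empty_removed, " without coded reactions)\n",
      "  duplicates removed:   ", x$n_duplicates_removed, "\n",
      "  output reports:       ", x$n_output, "\n", sep = "")
  invisible(x)
}
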