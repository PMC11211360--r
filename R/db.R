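# Core container for FAERS-style spontaneous report databases.
#
# A report_db is a small relational bundle, mirroring how FAERS itself is
# shipped: one row per case report plus long tables of drug mentions and
# reaction records keyed by report_id. report_id is unique per physical
# report row (a FAERS primaryid); case_id may repeat across versions until
# deduplicate() has run.

SEX_LEVELS <- c("female", "male", "unknown")
AGE_LEVELS <- c("<18", "18-64", ">=65", "unknown")
REPORTER_LEVELS <- c("healthcare_professional", "consumer", "unknown")
ROLE_LEVELS <- c("primary_suspect", "secondary_suspect", "concomitant",
                 "interacting")
SERIOUSNESS_LEVELS <- c("serious", "non_serious")
OUTCOME_LEVELS <- c("death", "life_threatening", "hospitalization",
                    "disability", "congenital_anomaly", "other_serious")

#' Construct a spontaneous-report database
#'
#' Bundles case reports, drug mentions and reaction records into a single
#' validated object, the common currency of the cleaning, contingency and
#' screening stages. The layout mirrors the FAERS quarterly extracts: one
#' demographic row per report plus long drug/reaction tables joined on
#' `report_id`.
#'
#' @param reports data.frame with one row per case report and columns
#'   `report_id`, `case_id`, `version`, `sex`, `age_group`, `weight_kg`,
#'   `country`, `reporter_type`, `received_year`, `event_date` (`Date`, may
#'   be `NA`), `seriousness`, `serious_outcomes` (`;`-joined subset of the
#'   regulatory serious-outcome codes, `""` when none).
#' @param drugs data.frame with columns `report_id`, `active_ingredient`,
#'   `product_name`, `role` (one of primary_suspect, secondary_suspect,
#'   concomitant, interacting), `reason_for_use`.
#' @param reactions data.frame with columns `report_id`, `pt` (MedDRA
#'   preferred term) and `soc` (its system organ class).
#' @param provenance free-text description of where the reports came from.
#' @param validate run the structural checks (disable only for trusted
#'   internal construction on hot paths).
#' @return An object of class `report_db`.
#' @export
report_db <- function(reports, drugs, reactions, provenance = "",
                      validate = TRUE) {
  reports <- as.data.frame(reports, stringsAsFactors = FALSE)
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  db <- structure(list(reports = reports, drugs = drugs,
                       reactions = reactions,
                       provenance = as.character(provenance)[1]),
                  class = "report_db")
  if (validate) validate_report_db(db)
  db
}

#' Number of case reports in a database
#' @param db a `report_db`.
#' @return integer count.
#' @export
n_reports <- function(db) nrow(db$reports)

#' @export
print.report_db <- function(x, ...) {
  cat("<report_db> ", nrow(x$reports), " reports, ",
      nrow(x$drugs), " drug mentions, ",
      nrow(x$reactions), " reaction records\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

validate_report_db <- function(db) {
  rep_cols <- c("report_id", "case_id", "version", "sex", "age_group",
                "weight_kg", "country", "reporter_type", "received_year",
                "event_date", "seriousness", "serious_outcomes")
  miss <- setdiff(rep_cols, names(db$reports))
  if (length(miss))
    stop("reports table lacks column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("report_id", "active_ingredient", "product_name", "role",
                    "reason_for_use"), names(db$drugs))
  if (length(miss))
    stop("drugs table lacks column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("report_id", "pt", "soc"), names(db$reactions))
  if (length(miss))
    stop("reactions table lacks column(s): ", paste(miss, collapse = ", "))

  r <- db$reports
  if (anyDuplicated(r$report_id))
    stop("report_id values must be unique")
  if (nrow(r)) {
    if (any(r$version < 0, na.rm = TRUE)) stop("version must be >= 0")
    if (any(r$received_year < 1968, na.rm = TRUE))
      stop("received_year must be >= 1968")
    chk_enum(r$sex, SEX_LEVELS, "sex")
    chk_enum(r$age_group, AGE_LEVELS, "age_group")
    chk_enum(r$reporter_type, REPORTER_LEVELS, "reporter_type")
    chk_enum(r$seriousness, SERIOUSNESS_LEVELS, "seriousness")
    # serious iff outcomes listed, when outcome detail is present
    has_outc <- !is.na(r$serious_outcomes) & nzchar(r$serious_outcomes)
    if (any(has_outc & r$seriousness != "serious"))
      stop("reports with serious outcomes must have seriousness = 'serious'")
    if (any(has_outc)) {
      toks <- unique(unlist(strsplit(r$serious_outcomes[has_outc], ";",
                                     fixed = TRUE)))
      bad <- setdiff(trimws(toks), OUTCOME_LEVELS)
      if (length(bad))
        stop("unknown serious outcome code(s): ", paste(bad, collapse = ", "))
    }
  }
  if (nrow(db$drugs)) {
    chk_enum(db$drugs$role, ROLE_LEVELS, "role")
    orphan <- setdiff(db$drugs$report_id, r$report_id)
    if (length(orphan))
      stop("drug mentions reference unknown report_id(s)")
  }
  if (nrow(db$reactions)) {
    orphan <- setdiff(db$reactions$report_id, r$report_id)
    if (length(orphan))
      stop("reaction records reference unknown report_id(s)")
  }
  invisible(db)
}

chk_enum <- function(x, levels, what) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad))
    stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "))
}

empty_reports_df <- function() {
  data.frame(report_id = character(), case_id = character(),
             version = integer(), sex = character(),
             age_group = character(), weight_kg = numeric(),
             country = character(), reporter_type = character(),
             received_year = integer(),
             event_date = as.Date(character()),
             seriousness = character(), serious_outcomes = character(),
             stringsAsFactors = FALSE)
}

empty_drugs_df <- function() {
  data.frame(report_id = character(), active_ingredient = character(),
             product_name = character(), role = character(),
             reason_for_use = character(), stringsAsFactors = FALSE)
}

empty_reactions_df <- function() {
  data.frame(report_id = character(), pt = character(), soc = character(),
             stringsAsFactors = FALSE)
}

#' An empty report database
#' @param provenance optional source description.
#' @return a `report_db` with zero reports.
#' @export
empty_report_db <- function(provenance = "empty") {
  report_db(empty_reports_df(), empty_drugs_df(), empty_reactions_df(),
            provenance = provenance)
}

#' Assign FAERS-style age groups
#'
#' Groups age in years into the bins used by descriptive tables:
#' `<18`, `18-64`, `>=65`, with missing ages mapped to `unknown`.
#' Boundary ages 18 and 65 fall into the higher bin.
#'
#' @param age_years numeric vector of ages in years (NA allowed).
#' @return character vector of age-group labels.
#' @export
age_to_group <- function(age_years) {
  out <- rep("unknown", length(age_years))
  ok <- !is.na(age_years)
  out[ok & age_years < 18] <- "<18"
  out[ok & age_years >= 18 & age_years < 65] <- "18-64"
  out[ok & age_years >= 65] <- ">=65"
  out
}

#' Normalise a drug name for matching
#'
#' FAERS drug names are free text; matching a target ingredient requires
#' case-folding and stripping whitespace and punctuation, so that
#' `"Esketamine "`, `"ESKETAMINE HYDROCHLORIDE"` and `"esketamine"` can be
#' compared on equal footing (the hydrochloride suffix is kept: only
#' spelling noise is removed, not salt forms).
#'
#' @param x character vector of drug names.
#' @return normalised upper-case alphanumeric strings.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(as.character(x))
  gsub("[^A-Z0-9]+", "", x)
}
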