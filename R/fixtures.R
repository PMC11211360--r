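# Reconstruction of a database from published marginal counts. The
# esketamine nasal spray safety profile ships as printed descriptive
# tables (case counts by demographic category; reaction-record counts by
# SOC); this builder lays out a synthetic database whose margins equal
# those counts exactly, so percentage recomputation can be checked against
# the printed values without the (non-redistributable) source database.

#' Published demographic margins for esketamine nasal spray
#'
#' The printed case counts by sex, age group, reporter type, country,
#' received year and seriousness (denominator: 6,887 de-duplicated
#' reports).
#'
#' @return data.frame with columns `block`, `category`, `count`.
#' @export
esketamine_demographic_counts <- function() {
  path <- system.file("extdata", "esk_demographic_counts.csv",
                      package = "pvsignal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "integer"))
}

#' Published SOC-level margins for esketamine nasal spray
#'
#' The printed reaction-record counts and screened-signal PT tallies per
#' system organ class (denominator: 14,606 adverse-event records over 25
#' SOCs).
#'
#' @return data.frame with columns `soc`, `count`, `signal_pts`.
#' @export
esketamine_soc_counts <- function() {
  path <- system.file("extdata", "esk_soc_counts.csv",
                      package = "pvsignal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Synthetic database matching the published esketamine margins
#'
#' Builds a deterministic `report_db` of 6,887 single-drug case reports
#' whose demographic marginal counts equal
#' [esketamine_demographic_counts()] and whose 14,606 reaction records
#' distribute over SOCs exactly as [esketamine_soc_counts()] (one
#' representative PT per SOC, each SOC at most once per case so the
#' event-record unit counts reproduce the margins). The joint distribution
#' across blocks is an arbitrary deterministic layout: only the margins
#' are meaningful. Every report carries esketamine as primary suspect.
#'
#' @return a `report_db`.
#' @export
esketamine_margins_db <- function() {
  dem <- esketamine_demographic_counts()
  socs <- esketamine_soc_counts()
  n <- sum(dem$count[dem$block == "sex"])

  expand <- function(block) {
    d <- dem[dem$block == block, ]
    rep(d$category, d$count)
  }
  country <- expand("country")
  # split the printed "Other" bucket into small synthetic countries so the
  # five real countries stay the top five
  n_other <- sum(country == "Other")
  filler <- rep(sprintf("XX%02d", 1:10),
                c(rep(n_other %/% 10, 9), n_other - 9 * (n_other %/% 10)))
  country[country == "Other"] <- filler

  seriousness <- expand("seriousness")
  reports <- data.frame(
    report_id = sprintf("E%05d", seq_len(n)),
    case_id = sprintf("E%05d", seq_len(n)),
    version = 0L,
    sex = expand("sex"),
    age_group = expand("age_group"),
    weight_kg = NA_real_,
    country = country,
    reporter_type = expand("reporter_type"),
    received_year = as.integer(expand("year")),
    event_date = as.Date("2021-06-15"),
    seriousness = seriousness,
    serious_outcomes = ifelse(seriousness == "serious",
                              "hospitalization", ""),
    stringsAsFactors = FALSE)

  drugs <- data.frame(report_id = reports$report_id,
                      active_ingredient = "esketamine",
                      product_name = "SPRAVATO",
                      role = "primary_suspect",
                      reason_for_use = "Treatment-resistant depression",
                      stringsAsFactors = FALSE)

  # one representative PT per SOC; lay records out cyclically so that a
  # SOC never repeats within one case (every SOC count <= case count)
  map <- default_pt_soc_map()
  rep_pt <- map$pt[match(socs$soc, map$soc)]
  if (anyNA(rep_pt))
    stop("bundled PT->SOC mapping lacks a PT for: ",
         paste(socs$soc[is.na(rep_pt)], collapse = "; "))
  total <- sum(socs$count)
  pos <- (cumsum(c(0, socs$count))[seq_len(nrow(socs))])
  case_idx <- unlist(lapply(seq_len(nrow(socs)), function(i)
    ((pos[i] + seq_len(socs$count[i]) - 1L) %% n) + 1L))
  reactions <- data.frame(
    report_id = reports$report_id[case_idx],
    pt = rep(rep_pt, socs$count),
    soc = rep(socs$soc, socs$count),
    stringsAsFactors = FALSE)

  db <- report_db(reports, drugs, reactions,
                  provenance = "synthetic reconstruction of published margins")
  stopifnot(nrow(db$reactions) == total)
  db
}
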