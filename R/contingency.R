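# The 2x2 "four-grid" counts for a target drug against the rest of the
# database: a = target drug & event, b = target drug & other events,
# c = other drugs & event, d = other drugs & other events.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d non-negative cell counts: target drug with the event,
#'   target drug with other events, other drugs with the event, other
#'   drugs with other events.
#' @param term optional event-term label.
#' @param level optional counting level (`"PT"` or `"SOC"`).
#' @return object of class `contingency_table` with fields `a,b,c,d`,
#'   `n` (= a+b+c+d), `term`, `level`.
#' @export
contingency_table <- function(a, b, c, d, term = NULL, level = NULL) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative counts")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 term = term, level = level),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  hdr <- if (!is.null(x$term)) paste0(" [", x$level, " ", x$term, "]") else ""
  cat("<contingency_table>", hdr, "\n", sep = "")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

# One countable record per (report, distinct term): identical PTs within a
# case collapse to one record; at SOC level, several PTs of one SOC also
# collapse to one record for that case.
reaction_records <- function(db, level = c("PT", "SOC")) {
  level <- match.arg(level)
  re <- db$reactions
  term <- if (level == "PT") re$pt else re$soc
  rec <- data.frame(report_id = re$report_id, term = term,
                    stringsAsFactors = FALSE)
  rec[!duplicated(paste(rec$report_id, rec$term, sep = "\r")), , drop = FALSE]
}

#' Build the four-grid table for one drug-event pair
#'
#' Counts the a/b/c/d cells for a target drug against every other drug in
#' the database, at PT or SOC level. With the default
#' `counting_unit = "event_record"` each distinct (case, term) pair is one
#' countable record, so a case reporting three different PTs contributes
#' three records; this is the unit under which per-SOC record counts sum
#' to the total adverse-event record count. With `counting_unit = "case"`
#' each case counts exactly once, landing in `a` (or `c`) when it contains
#' the event and `b` (or `d`) otherwise.
#'
#' @param db a cleaned `report_db`.
#' @param target_ingredient target drug active ingredient.
#' @param event_term the PT (or SOC) of interest.
#' @param level `"PT"` or `"SOC"`.
#' @param counting_unit `"event_record"` or `"case"`.
#' @param role,aliases target-drug matching, as in
#'   [select_target_reports()].
#' @return a `contingency_table`. A term absent from the whole database
#'   yields `a = c = 0` (a valid table that will fail screening), not an
#'   error; an empty database is a precondition violation.
#' @export
build_contingency <- function(db, target_ingredient, event_term,
                              level = c("PT", "SOC"),
                              counting_unit = c("event_record", "case"),
                              role = "primary_suspect",
                              aliases = character()) {
  level <- match.arg(level)
  counting_unit <- match.arg(counting_unit)
  if (!nrow(db$reports)) stop("empty database: no analyzable records (N = 0)")
  is_tgt <- is_target_report(db, target_ingredient, role, aliases)
  tgt_ids <- db$reports$report_id[is_tgt]
  rec <- reaction_records(db, level)
  rec_tgt <- rec$report_id %in% tgt_ids
  if (counting_unit == "event_record") {
    hit <- rec$term == event_term
    a <- sum(rec_tgt & hit); b <- sum(rec_tgt & !hit)
    c <- sum(!rec_tgt & hit); d <- sum(!rec_tgt & !hit)
  } else {
    with_term <- unique(rec$report_id[rec$term == event_term])
    rep_tgt <- db$reports$report_id %in% tgt_ids
    rep_hit <- db$reports$report_id %in% with_term
    a <- sum(rep_tgt & rep_hit); b <- sum(rep_tgt & !rep_hit)
    c <- sum(!rep_tgt & rep_hit); d <- sum(!rep_tgt & !rep_hit)
  }
  contingency_table(a, b, c, d, term = event_term, level = level)
}

#' Build four-grid tables for every event term of the target drug
#'
#' Sweeps all distinct terms observed on target-drug records (terms never
#' reported with the target drug are omitted: their `a` would be 0) and
#' returns one `contingency_table` per term, in a single vectorised pass.
#'
#' @inheritParams build_contingency
#' @return named list of `contingency_table`s, alphabetical by term;
#'   empty when the target drug is absent.
#' @export
build_all_contingencies <- function(db, target_ingredient,
                                    level = c("PT", "SOC"),
                                    counting_unit = c("event_record", "case"),
                                    role = "primary_suspect",
                                    aliases = character()) {
  level <- match.arg(level)
  counting_unit <- match.arg(counting_unit)
  if (!nrow(db$reports)) return(structure(list(), names = character()))
  is_tgt <- is_target_report(db, target_ingredient, role, aliases)
  tgt_ids <- db$reports$report_id[is_tgt]
  rec <- reaction_records(db, level)
  rec_tgt <- rec$report_id %in% tgt_ids
  terms <- sort(unique(rec$term[rec_tgt]))
  if (!length(terms)) return(structure(list(), names = character()))

  if (counting_unit == "event_record") {
    a_tab <- table(factor(rec$term[rec_tgt], levels = terms))
    c_tab <- table(factor(rec$term[!rec_tgt], levels = terms))
    tot_t <- sum(rec_tgt); tot_o <- sum(!rec_tgt)
    tabs <- lapply(seq_along(terms), function(i) {
      a <- as.integer(a_tab[i]); c <- as.integer(c_tab[i])
      contingency_table(a, tot_t - a, c, tot_o - c,
                        term = terms[i], level = level)
    })
  } else {
    n_t <- length(tgt_ids); n_o <- nrow(db$reports) - n_t
    a_tab <- table(factor(rec$term[rec_tgt], levels = terms))
    c_tab <- table(factor(rec$term[!rec_tgt], levels = terms))
    tabs <- lapply(seq_along(terms), function(i) {
      a <- as.integer(a_tab[i]); c <- as.integer(c_tab[i])
      contingency_table(a, n_t - a, c, n_o - c,
                        term = terms[i], level = level)
    })
  }
  names(tabs) <- terms
  tabs
}
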