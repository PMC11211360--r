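# Descriptive outputs: the demographic table (case denominator), the
# SOC-level table (reaction-record denominator) and the top-N PT ranking.
# The two denominators coexist on purpose: demographic blocks describe
# cases, SOC blocks describe adverse-event records, and each output
# labels which one it uses.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed pharmacovigilance
#' tables conventionally round half up, so 17.395 becomes 17.40.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

pct_block <- function(counts, denominator) {
  data.frame(category = names(counts),
             count = as.integer(counts),
             percent = round_half_up(100 * as.integer(counts) / denominator),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Demographic and descriptive summary of a report database
#'
#' Per-category counts and percentages for sex, age group, reporter type,
#' reporting country (top `k` by count), received year and seriousness,
#' each over the case-count denominator, with percentages rounded half-up
#' to two decimals.
#'
#' @param db a cleaned `report_db`.
#' @param top_countries how many countries to list individually.
#' @return object of class `demographics_summary`: a named list of
#'   data.frames (`sex`, `age_group`, `reporter_type`, `country`, `year`,
#'   `seriousness`) plus `denominator`, the case count.
#' @export
demographics_summary <- function(db, top_countries = 5) {
  r <- db$reports
  n <- nrow(r)
  blk <- function(x, levels = NULL) {
    tab <- if (is.null(levels)) table(x) else table(factor(x, levels = levels))
    pct_block(tab, n)
  }
  country_tab <- sort(table(r$country), decreasing = TRUE)
  k <- min(top_countries, length(country_tab))
  country <- pct_block(country_tab[seq_len(k)], n)

  out <- list(
    sex = blk(r$sex, SEX_LEVELS),
    age_group = blk(r$age_group, AGE_LEVELS),
    reporter_type = blk(r$reporter_type, REPORTER_LEVELS),
    country = country,
    year = blk(r$received_year),
    seriousness = blk(r$seriousness, SERIOUSNESS_LEVELS),
    denominator = n)
  class(out) <- "demographics_summary"
  out
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat("Descriptive summary (denominator: ", x$denominator,
      " case reports)\n", sep = "")
  for (b in c("sex", "age_group", "reporter_type", "country", "year",
              "seriousness")) {
    cat("\n", gsub("_", " ", b), ":\n", sep = "")
    print(x[[b]], row.names = FALSE)
  }
  invisible(x)
}

#' SOC-level record counts and signal tallies
#'
#' Per system organ class: the number of reaction records (event-record
#' unit, one per distinct case-PT pair mapped into the SOC), the
#' percentage of all reaction records, and -- when a PT-level screen
#' result is supplied -- how many screened signal PTs fall in the SOC,
#' both as the conjunction count (`signals`) and per criterion.
#'
#' @param db a cleaned `report_db`.
#' @param screen_result optional `signal_screen` from [screen_signals()]
#'   at PT level.
#' @return object of class `soc_summary`: data.frame with columns `soc`,
#'   `count`, `percent` and (with a screen) `signals`, `signals_ror`,
#'   `signals_prr`, `signals_ebgm`, plus attribute `denominator` (total
#'   reaction records).
#' @export
soc_summary <- function(db, screen_result = NULL) {
  rec <- reaction_records(db, "SOC")
  tab <- sort(table(rec$term), decreasing = TRUE)
  total <- sum(tab)
  out <- data.frame(soc = names(tab), count = as.integer(tab),
                    percent = round_half_up(100 * as.integer(tab) / total),
                    stringsAsFactors = FALSE)
  if (!is.null(screen_result)) {
    stopifnot(inherits(screen_result, "signal_screen"))
    if (screen_result$level != "PT")
      stop("soc_summary needs a PT-level screen result")
    s <- screen_result$stats
    cnt <- function(flag) {
      t <- table(factor(s$soc[flag], levels = out$soc))
      as.integer(t)
    }
    out$signals <- cnt(s$is_signal)
    out$signals_ror <- cnt(s$flag_ror)
    out$signals_prr <- cnt(s$flag_prr)
    out$signals_ebgm <- cnt(s$flag_ebgm)
  }
  attr(out, "denominator") <- total
  class(out) <- c("soc_summary", "data.frame")
  out
}

#' @export
print.soc_summary <- function(x, ...) {
  cat("SOC-level summary (denominator: ", attr(x, "denominator"),
      " reaction records)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Top-ranked signal terms
#'
#' Orders the screened terms by a ranking statistic (EBGM by default,
#' descending), breaking ties by larger `n` then alphabetical term, and
#' returns the first `k`. By default only terms passing the screen are
#' ranked.
#'
#' @param screen_result a `signal_screen` (or its `stats` data.frame).
#' @param k number of terms to return (default 50); `k <= 0` gives an
#'   empty list.
#' @param rank_key column to rank by (default `"ebgm"`).
#' @param signals_only rank only terms with `is_signal = TRUE`.
#' @return data.frame of the top `k` rows, ordered.
#' @export
top_signals <- function(screen_result, k = 50, rank_key = "ebgm",
                        signals_only = TRUE) {
  s <- if (inherits(screen_result, "signal_screen")) screen_result$stats
       else as.data.frame(screen_result)
  if (k <= 0) return(s[0, , drop = FALSE])
  if (signals_only && "is_signal" %in% names(s))
    s <- s[s$is_signal, , drop = FALSE]
  if (!nrow(s)) return(s)
  key <- s[[rank_key]]
  key[is.na(key)] <- -Inf
  ord <- order(-key, -s$n, s$term)
  s <- s[ord, , drop = FALSE]
  rownames(s) <- NULL
  utils::head(s, k)
}
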