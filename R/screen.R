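# The end-to-end screen: sweep every event term of the target drug,
# compute all disproportionality statistics, apply the thresholds, and
# return a classed result object.

#' Screen every event term of a target drug for disproportionality signals
#'
#' Builds the 2x2 table for each PT (or SOC) observed on target-drug
#' reports, computes ROR, PRR, EBGM and chi-squared with confidence
#' intervals, and applies the screening criteria. The result carries one
#' row per term with per-criterion flags and the overall `is_signal`
#' verdict; filter on `is_signal` (or use [top_signals()]) for the
#' screened subset.
#'
#' @param db a cleaned `report_db` (run [clean_reports()] first on raw
#'   data).
#' @param target target drug active ingredient.
#' @param level `"PT"` or `"SOC"`.
#' @param criteria a [signal_criteria()].
#' @param ebgm_mode `"rr"`: report the unshrunk relative reporting ratio
#'   under the EBGM label, with its Woolf lower bound as EBGM05 (the
#'   spreadsheet convention); `"mgps"`: fit (or use) a gamma-mixture prior
#'   and report the shrunk empirical-Bayes EBGM with posterior EB05/EB95.
#' @param counting_unit `"event_record"` (default) or `"case"`, as in
#'   [build_contingency()].
#' @param role,aliases target-drug matching, as in
#'   [select_target_reports()].
#' @param prior optional pre-fitted [gps_prior] for `ebgm_mode = "mgps"`;
#'   fitted on the swept tables when omitted.
#' @param yates Yates-corrected chi-squared.
#' @param zero_correction zero-cell policy, as in [compute_ror()].
#' @return object of class `signal_screen`: a list with `stats` (one row
#'   per term: term, soc, n, estimates, CIs, flags), `criteria`, `level`,
#'   `ebgm_mode`, `target`, `counting_unit`, `n_target_records`,
#'   `n_total_records`, `n_reports` and (for mgps) `prior`.
#' @export
screen_signals <- function(db, target, level = c("PT", "SOC"),
                           criteria = signal_criteria(),
                           ebgm_mode = c("rr", "mgps"),
                           counting_unit = c("event_record", "case"),
                           role = "primary_suspect", aliases = character(),
                           prior = NULL, yates = TRUE,
                           zero_correction = c("none", "haldane")) {
  level <- match.arg(level)
  ebgm_mode <- match.arg(ebgm_mode)
  counting_unit <- match.arg(counting_unit)
  zero_correction <- match.arg(zero_correction)

  tabs <- build_all_contingencies(db, target, level, counting_unit,
                                  role, aliases)
  if (ebgm_mode == "mgps" && is.null(prior) && length(tabs))
    prior <- fit_gps_prior(tabs)

  rows <- lapply(tabs, evaluate_signal, criteria = criteria,
                 ebgm_mode = ebgm_mode, prior = prior, yates = yates,
                 zero_correction = zero_correction)
  stats <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
           else evaluate_signal(contingency_table(1, 1, 1, 1))[0, ]
  class(stats) <- "data.frame"

  if (level == "PT" && nrow(stats)) {
    soc_of <- db$reactions$soc[match(stats$term, db$reactions$pt)]
    stats <- cbind(stats[, "term", drop = FALSE], soc = soc_of,
                   stats[, setdiff(names(stats), "term"), drop = FALSE])
  } else if (nrow(stats)) {
    stats <- cbind(stats[, "term", drop = FALSE], soc = stats$term,
                   stats[, setdiff(names(stats), "term"), drop = FALSE])
  } else {
    stats$soc <- character(0)
  }
  rownames(stats) <- NULL

  n_tgt <- if (length(tabs)) tabs[[1]]$a + tabs[[1]]$b else 0L
  n_tot <- if (length(tabs)) tabs[[1]]$n else 0L
  structure(list(stats = stats, criteria = criteria, level = level,
                 ebgm_mode = ebgm_mode, target = target,
                 counting_unit = counting_unit,
                 n_target_records = n_tgt, n_total_records = n_tot,
                 n_reports = nrow(db$reports), prior = prior),
            class = "signal_screen")
}

#' @export
print.signal_screen <- function(x, ...) {
  cat("<signal_screen> target = ", x$target, ", level = ", x$level,
      ", unit = ", x$counting_unit, ", ebgm = ", x$ebgm_mode, "\n",
      "  ", nrow(x$stats), " event terms swept; ",
      sum(x$stats$is_signal), " pass the screen (",
      x$n_target_records, " target records of ", x$n_total_records,
      " total)\n", sep = "")
  invisible(x)
}

#' @export
summary.signal_screen <- function(object, k = 10, ...) {
  s <- object$stats
  out <- list(
    target = object$target, level = object$level,
    n_terms = nrow(s),
    n_flag_ror = sum(s$flag_ror), n_flag_prr = sum(s$flag_prr),
    n_flag_ebgm = sum(s$flag_ebgm), n_signals = sum(s$is_signal),
    top = top_signals(object, k = k))
  class(out) <- "summary.signal_screen"
  out
}

#' @export
print.summary.signal_screen <- function(x, ...) {
  cat("Signal screen for ", x$target, " (", x$level, " level)\n",
      "  terms swept:      ", x$n_terms, "\n",
      "  ROR criterion:    ", x$n_flag_ror, "\n",
      "  PRR criterion:    ", x$n_flag_prr, "\n",
      "  EBGM criterion:   ", x$n_flag_ebgm, "\n",
      "  overall signals:  ", x$n_signals, "\n\n", sep = "")
  if (nrow(x$top)) {
    cat("Top terms by EBGM:\n")
    show <- x$top[, c("term", "n", "ror", "prr", "ebgm", "ebgm05")]
    show[, 3:6] <- lapply(show[, 3:6], function(v) round(v, 2))
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.signal_screen <- function(x, ...) x$stats

#' @export
plot.signal_screen <- function(x, k = 20, ...) {
  s <- top_signals(x, k = k)
  if (!nrow(s)) {
    warning("no signals to plot")
    return(invisible(x))
  }
  s <- s[rev(seq_len(nrow(s))), ]
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(log10(s$ebgm), names.arg = s$term, horiz = TRUE,
                    las = 1, cex.names = 0.7, col = "steelblue",
                    xlab = "log10(EBGM)",
                    main = paste("Top", nrow(s), "signals:", x$target))
  invisible(x)
}
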