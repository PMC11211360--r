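# Classical disproportionality statistics on a 2x2 table, with Woolf-type
# log-normal confidence intervals:
#
#   ROR  = (a/b)/(c/d) = ad/bc,  CI = exp(ln ROR +- z*sqrt(1/a+1/b+1/c+1/d))
#   PRR  = (a/(a+b))/(c/(c+d)), CI = exp(ln PRR +- z*sqrt(1/a-1/(a+b)+1/c-1/(c+d)))
#   RR   = a*N/((a+c)(a+b))     (the relative reporting ratio, printed as
#          "EBGM" in many pharmacovigilance reports; its lower CI bound is
#          then reported as EBGM05), CI as for the ROR.
#
# Zero cells leave a statistic undefined (NA, screening flag fails) unless
# the Haldane +0.5 correction is requested.

cells_of <- function(table) {
  if (inherits(table, "contingency_table"))
    c(a = table$a, b = table$b, c = table$c, d = table$d)
  else if (is.numeric(table) && length(table) == 4)
    c(a = table[[1]], b = table[[2]], c = table[[3]], d = table[[4]])
  else stop("expected a contingency_table or a numeric vector (a,b,c,d)")
}

apply_zero_correction <- function(ab, correction) {
  if (correction == "haldane" && any(ab == 0)) ab + 0.5 else ab
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = ad/bc`, the odds of the event among target-drug reports versus
#' all other reports, with the log-normal interval
#' `exp(ln ROR +- z*sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param table a [contingency_table()] (or numeric `c(a,b,c,d)`).
#' @param z normal quantile for the interval (1.96 for 95%).
#' @param zero_correction `"none"` (a zero cell makes the statistic
#'   undefined, returned as `NA`) or `"haldane"` (+0.5 on every cell when
#'   any cell is zero).
#' @return named numeric: `estimate`, `ci_low`, `ci_high`.
#' @export
compute_ror <- function(table, z = 1.96,
                        zero_correction = c("none", "haldane")) {
  zero_correction <- match.arg(zero_correction)
  x <- apply_zero_correction(cells_of(table), zero_correction)
  if (any(x == 0))
    return(c(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  est <- unname((x["a"] * x["d"]) / (x["b"] * x["c"]))
  se <- sqrt(sum(1 / x))
  ci <- exp(log(est) + c(-1, 1) * z * se)
  c(estimate = est, ci_low = ci[1], ci_high = ci[2])
}

#' Proportional reporting ratio with confidence interval
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`, the event's share of target-drug records
#' relative to its share of all other records, with interval
#' `exp(ln PRR +- z*sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#'
#' @inheritParams compute_ror
#' @return named numeric: `estimate`, `ci_low`, `ci_high`.
#' @export
compute_prr <- function(table, z = 1.96,
                        zero_correction = c("none", "haldane")) {
  zero_correction <- match.arg(zero_correction)
  x <- apply_zero_correction(cells_of(table), zero_correction)
  if (x["a"] == 0 || x["c"] == 0 || x["a"] + x["b"] == 0 ||
      x["c"] + x["d"] == 0)
    return(c(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  est <- unname((x["a"] / (x["a"] + x["b"])) / (x["c"] / (x["c"] + x["d"])))
  se2 <- unname(1 / x["a"] - 1 / (x["a"] + x["b"]) + 1 / x["c"] -
                  1 / (x["c"] + x["d"]))
  ci <- exp(log(est) + c(-1, 1) * z * sqrt(se2))
  c(estimate = est, ci_low = ci[1], ci_high = ci[2])
}

#' Relative reporting ratio (the "EBGM" of spreadsheet practice)
#'
#' `RR = a * N / ((a+c)(a+b))` with `N = a+b+c+d`: the observed count over
#' the count expected under row-column independence. Spreadsheet
#' pharmacovigilance analyses commonly print this unshrunk ratio under the
#' label EBGM, reporting its lower confidence bound
#' `exp(ln RR - z*sqrt(1/a+1/b+1/c+1/d))` as EBGM05; the genuinely shrunk
#' empirical-Bayes version is [compute_mgps_ebgm()].
#'
#' @inheritParams compute_ror
#' @return named numeric: `estimate`, `ci_low`, `ci_high`.
#' @export
compute_rr_ebgm <- function(table, z = 1.96,
                            zero_correction = c("none", "haldane")) {
  zero_correction <- match.arg(zero_correction)
  x <- apply_zero_correction(cells_of(table), zero_correction)
  if (any(x == 0))
    return(c(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  n <- sum(x)
  est <- unname(x["a"] * n / ((x["a"] + x["c"]) * (x["a"] + x["b"])))
  se <- sqrt(sum(1 / x))
  ci <- exp(log(est) + c(-1, 1) * z * se)
  c(estimate = est, ci_low = ci[1], ci_high = ci[2])
}

#' Pearson chi-squared for a 2x2 table
#'
#' The companion statistic usually reported next to the PRR. With
#' `yates = TRUE` (default) applies the continuity correction:
#' `N(|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`; without it, the plain
#' Pearson statistic. A zero margin leaves the statistic undefined.
#'
#' @param table a [contingency_table()] (or numeric `c(a,b,c,d)`).
#' @param yates apply the Yates continuity correction.
#' @return the chi-squared value (scalar; `NA` if undefined).
#' @export
compute_chi2 <- function(table, yates = TRUE) {
  x <- cells_of(table)
  n <- sum(x)
  if (n == 0) return(NA_real_)
  m <- c(x["a"] + x["b"], x["c"] + x["d"], x["a"] + x["c"], x["b"] + x["d"])
  if (any(m == 0)) return(NA_real_)
  dev <- abs(x["a"] * x["d"] - x["b"] * x["c"])
  if (yates) dev <- max(0, dev - n / 2)
  unname(n * dev^2 / prod(m))
}

#' Screening thresholds for signal detection
#'
#' The conventional multi-method screen: a term is flagged by ROR (or PRR)
#' when its count `a >= min_a` and the 95% CI lower limit exceeds
#' `ci_low_threshold`; flagged by EBGM when `EBGM05 > ebgm05_threshold`.
#' `combine` controls whether the overall signal requires all criteria or
#' any one of them.
#'
#' @param min_a minimum event count (default 3).
#' @param ci_low_threshold lower-CI threshold for ROR and PRR (default 1).
#' @param ebgm05_threshold EBGM05 threshold (default 2).
#' @param conf_level confidence level of the intervals; `z` is its normal
#'   quantile (1.96 at the default 0.95).
#' @param combine `"all"` (conjunction, default) or `"any"`.
#' @return object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_a = 3, ci_low_threshold = 1,
                            ebgm05_threshold = 2, conf_level = 0.95,
                            combine = c("all", "any")) {
  combine <- match.arg(combine)
  stopifnot(min_a >= 1, conf_level > 0, conf_level < 1)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (abs(conf_level - 0.95) < 1e-12) z <- 1.96  # the conventional quantile
  structure(list(min_a = min_a, ci_low_threshold = ci_low_threshold,
                 ebgm05_threshold = ebgm05_threshold,
                 conf_level = conf_level, z = z, combine = combine),
            class = "signal_criteria")
}

#' @export
print.signal_criteria <- function(x, ...) {
  cat("<signal_criteria> a >= ", x$min_a,
      "; ROR/PRR ", 100 * x$conf_level, "% CI lower limit > ",
      x$ci_low_threshold, "; EBGM05 > ", x$ebgm05_threshold,
      "; combine = ", x$combine, "\n", sep = "")
  invisible(x)
}

#' Compute all statistics for one table and apply the screen
#'
#' Evaluates ROR, PRR, the EBGM-labelled relative reporting ratio (or, when
#' `prior` is supplied, the shrunk MGPS EBGM) and chi-squared on one
#' contingency table, then sets the per-criterion flags and the overall
#' `is_signal`. An undefined statistic fails its flag.
#'
#' @param table a [contingency_table()].
#' @param criteria a [signal_criteria()].
#' @param ebgm_mode `"rr"` for the unshrunk relative reporting ratio,
#'   `"mgps"` for the empirical-Bayes shrinker (needs `prior`).
#' @param prior a [gps_prior] when `ebgm_mode = "mgps"`.
#' @param yates use the Yates-corrected chi-squared.
#' @param zero_correction zero-cell policy, as in [compute_ror()].
#' @return one-row data.frame of class `signal_statistics` with the
#'   estimates, CIs, flags and `is_signal`.
#' @export
evaluate_signal <- function(table, criteria = signal_criteria(),
                            ebgm_mode = c("rr", "mgps"),
                            prior = NULL, yates = TRUE,
                            zero_correction = c("none", "haldane")) {
  ebgm_mode <- match.arg(ebgm_mode)
  zero_correction <- match.arg(zero_correction)
  z <- criteria$z
  ror <- compute_ror(table, z, zero_correction)
  prr <- compute_prr(table, z, zero_correction)
  if (ebgm_mode == "mgps") {
    if (is.null(prior)) stop("ebgm_mode = 'mgps' requires a fitted prior")
    # EB05/EB95 are by convention the 5th/95th posterior percentiles
    eb <- compute_mgps_ebgm(table, prior, probs = c(0.05, 0.95))
  } else {
    eb <- compute_rr_ebgm(table, z, zero_correction)
  }
  chi2 <- compute_chi2(table, yates)
  n <- cells_of(table)[["a"]]

  pass_ci <- function(lo) !is.na(lo) && lo > criteria$ci_low_threshold
  flag_ror <- n >= criteria$min_a && pass_ci(ror[["ci_low"]])
  flag_prr <- n >= criteria$min_a && pass_ci(prr[["ci_low"]])
  flag_ebgm <- !is.na(eb[["ci_low"]]) &&
    eb[["ci_low"]] > criteria$ebgm05_threshold
  is_signal <- if (criteria$combine == "all")
    flag_ror && flag_prr && flag_ebgm else flag_ror || flag_prr || flag_ebgm

  out <- data.frame(
    term = if (is.null(table$term)) NA_character_ else table$term,
    level = if (is.null(table$level)) NA_character_ else table$level,
    n = n,
    ror = ror[["estimate"]], ror_low = ror[["ci_low"]],
    ror_high = ror[["ci_high"]],
    prr = prr[["estimate"]], prr_low = prr[["ci_low"]],
    prr_high = prr[["ci_high"]],
    ebgm = eb[["estimate"]], ebgm05 = eb[["ci_low"]],
    ebgm95 = eb[["ci_high"]],
    chi2 = chi2,
    flag_ror = flag_ror, flag_prr = flag_prr, flag_ebgm = flag_ebgm,
    is_signal = is_signal,
    stringsAsFactors = FALSE)
  class(out) <- c("signal_statistics", class(out))
  out
}
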