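# DuMouchel-style multi-item gamma Poisson shrinker (MGPS).
#
# Model: observed count a ~ Poisson(lambda * E) with E the count expected
# under independence, and lambda drawn from a two-component gamma mixture
#   lambda ~ w * Gamma(alpha1, beta1) + (1 - w) * Gamma(alpha2, beta2)
# (shape/rate). Marginally a is a mixture of negative binomials; the prior
# is fitted by maximum likelihood over all (a, E) cells, and the posterior
# for each cell is again a gamma mixture, giving
#   EBGM = exp(E[ln lambda | a, E])   and   EB05/EB95 posterior quantiles.

#' Expected count of a contingency table under independence
#'
#' `E = (a+c)(a+b)/N`: the count expected in cell `a` if the drug and the
#' event were reported independently.
#'
#' @param table a [contingency_table()] (or numeric `c(a,b,c,d)`).
#' @return scalar expected count.
#' @export
expected_count <- function(table) {
  x <- cells_of(table)
  unname((x["a"] + x["c"]) * (x["a"] + x["b"]) / sum(x))
}

gps_cells <- function(tables) {
  if (is.data.frame(tables)) {
    stopifnot(all(c("a", "E") %in% names(tables)))
    return(tables[, c("a", "E")])
  }
  a <- vapply(tables, function(t) cells_of(t)[["a"]], numeric(1))
  E <- vapply(tables, expected_count, numeric(1))
  data.frame(a = a, E = E)
}

gps_nll <- function(theta, a, E) {
  al1 <- exp(theta[1]); be1 <- exp(theta[2])
  al2 <- exp(theta[3]); be2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  f1 <- suppressWarnings(stats::dnbinom(a, size = al1,
                                        prob = be1 / (be1 + E)))
  f2 <- suppressWarnings(stats::dnbinom(a, size = al2,
                                        prob = be2 / (be2 + E)))
  ll <- log(w * f1 + (1 - w) * f2)
  if (!all(is.finite(ll))) return(1e12)
  -sum(ll)
}

# deterministic multi-start grid; first entry is the classical
# DuMouchel starting point
GPS_STARTS <- list(
  c(0.2, 0.1, 2, 4, 1 / 3),
  c(1, 1, 1, 1, 0.5),
  c(0.5, 0.5, 5, 5, 0.2),
  c(0.1, 0.05, 1, 2, 0.1),
  c(2, 2, 0.2, 0.2, 0.5),
  c(5, 10, 0.5, 0.1, 0.8))

#' Fit the gamma-mixture prior of the MGPS by maximum likelihood
#'
#' Maximises the negative-binomial mixture marginal likelihood of all
#' (observed count, expected count) cells over the five prior parameters
#' (two gamma shapes, two gamma rates, one mixture weight), using a fixed
#' grid of starting points and BFGS on transformed (log / logit)
#' parameters, so the fit is deterministic and invariant to cell order.
#'
#' @param tables a list of [contingency_table()]s, or a data.frame with
#'   columns `a` (observed count) and `E` (expected count).
#' @param min_cells minimum number of cells required for a stable fit.
#' @return object of class `gps_prior`: `alpha1`, `beta1`, `alpha2`,
#'   `beta2`, `w`, plus `loglik` and `n_cells`. If no start converges, an
#'   error of class `gps_convergence_error` is signalled carrying the
#'   best-so-far parameters in its `best` field.
#' @export
fit_gps_prior <- function(tables, min_cells = 50) {
  cells <- gps_cells(tables)
  a <- cells$a; E <- cells$E
  keep <- is.finite(a) & is.finite(E) & E > 0
  a <- a[keep]; E <- E[keep]
  if (length(a) < min_cells)
    stop("fit_gps_prior needs at least ", min_cells,
         " drug-event cells with positive expected counts (got ",
         length(a), ")")

  best <- NULL; best_ok <- FALSE
  for (start in GPS_STARTS) {
    theta0 <- c(log(start[1:4]), stats::qlogis(start[5]))
    fit <- tryCatch(
      stats::optim(theta0, gps_nll, a = a, E = E, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best_ok <- best_ok || fit$convergence == 0
    } else if (fit$convergence == 0 &&
               fit$value <= best$value + 1e-6) best_ok <- TRUE
  }
  if (is.null(best))
    stop("fit_gps_prior: all optimisation starts failed")
  prior <- theta_to_prior(best$par, -best$value, length(a))
  if (!best_ok) {
    cond <- structure(
      class = c("gps_convergence_error", "error", "condition"),
      list(message = paste0("fit_gps_prior did not converge from any start",
                            " (best log-likelihood ", format(-best$value),
                            "); best-so-far parameters attached"),
           call = sys.call(-1), best = prior))
    stop(cond)
  }
  prior
}

theta_to_prior <- function(theta, loglik, n_cells) {
  structure(list(alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
                 alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
                 w = stats::plogis(theta[5]),
                 loglik = loglik, n_cells = n_cells),
            class = "gps_prior")
}

#' Construct a gamma-mixture prior directly
#'
#' @param alpha1,beta1,alpha2,beta2 positive gamma shape/rate parameters.
#' @param w mixture weight of the first component, in (0, 1).
#' @return object of class `gps_prior`.
#' @export
gps_prior <- function(alpha1, beta1, alpha2, beta2, w) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, w > 0, w < 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w, loglik = NA_real_,
                 n_cells = NA_integer_),
            class = "gps_prior")
}

#' @export
print.gps_prior <- function(x, ...) {
  cat("<gps_prior> lambda ~ ", format(x$w, digits = 4),
      " * Gamma(", format(x$alpha1, digits = 4), ", ",
      format(x$beta1, digits = 4), ") + ",
      format(1 - x$w, digits = 4), " * Gamma(",
      format(x$alpha2, digits = 4), ", ", format(x$beta2, digits = 4),
      ")\n", sep = "")
  if (!is.na(x$loglik))
    cat("  fitted on ", x$n_cells, " cells, log-likelihood ",
        format(x$loglik), "\n", sep = "")
  invisible(x)
}

#' @export
coef.gps_prior <- function(object, ...) {
  c(alpha1 = object$alpha1, beta1 = object$beta1,
    alpha2 = object$alpha2, beta2 = object$beta2, w = object$w)
}

#' @export
logLik.gps_prior <- function(object, ...) {
  structure(object$loglik, df = 5L, nobs = object$n_cells,
            class = "logLik")
}

# Posterior mixture weight of component 1 for one (a, E) cell
posterior_weight <- function(a, E, p) {
  l1 <- log(p$w) + stats::dnbinom(a, size = p$alpha1,
                                  prob = p$beta1 / (p$beta1 + E), log = TRUE)
  l2 <- log(1 - p$w) + stats::dnbinom(a, size = p$alpha2,
                                      prob = p$beta2 / (p$beta2 + E),
                                      log = TRUE)
  m <- pmax(l1, l2)
  exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
}

mixture_cdf <- function(q, a, E, p, q1w) {
  q1w * stats::pgamma(q, shape = p$alpha1 + a, rate = p$beta1 + E) +
    (1 - q1w) * stats::pgamma(q, shape = p$alpha2 + a, rate = p$beta2 + E)
}

mixture_quantile <- function(prob, a, E, p, q1w, tol = 1e-8) {
  # bracket with the component quantiles, then bisect the mixture CDF
  q1 <- stats::qgamma(prob, shape = p$alpha1 + a, rate = p$beta1 + E)
  q2 <- stats::qgamma(prob, shape = p$alpha2 + a, rate = p$beta2 + E)
  lo <- min(q1, q2); hi <- max(q1, q2)
  if (hi - lo < tol) return((lo + hi) / 2)
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (mixture_cdf(mid, a, E, p, q1w) < prob) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Empirical-Bayes EBGM and posterior quantiles for one cell
#'
#' Given a fitted [gps_prior], the posterior of the reporting-rate ratio
#' lambda for a cell with observed count `a` and expected count `E` is a
#' mixture of `Gamma(alpha_k + a, beta_k + E)`. EBGM is the geometric mean
#' of that posterior, `exp(E[ln lambda])`, computed with the digamma
#' function; EB05 and EB95 are posterior quantiles found by bisection on
#' the mixture CDF (tolerance 1e-8).
#'
#' @param table a [contingency_table()] (or numeric `c(a,b,c,d)`).
#' @param prior a `gps_prior`.
#' @param probs lower/upper posterior quantiles to report.
#' @return named numeric: `estimate` (EBGM), `ci_low` (EB05), `ci_high`
#'   (EB95).
#' @export
compute_mgps_ebgm <- function(table, prior, probs = c(0.05, 0.95)) {
  x <- cells_of(table)
  a <- x[["a"]]
  E <- expected_count(x)
  if (!is.finite(E) || E <= 0)
    return(c(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  p <- prior
  q1w <- posterior_weight(a, E, p)
  ln_mean <- q1w * (digamma(p$alpha1 + a) - log(p$beta1 + E)) +
    (1 - q1w) * (digamma(p$alpha2 + a) - log(p$beta2 + E))
  c(estimate = exp(ln_mean),
    ci_low = mixture_quantile(probs[1], a, E, p, q1w),
    ci_high = mixture_quantile(probs[2], a, E, p, q1w))
}
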