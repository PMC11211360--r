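# Gamma-Poisson shrinker: closed-form posterior checks, prior recovery,
# shrinkage behaviour.

# independent closed-form EBGM for a gamma-mixture prior
ebgm_closed_form <- function(a, E, p) {
  f1 <- dnbinom(a, size = p$alpha1, prob = p$beta1 / (p$beta1 + E))
  f2 <- dnbinom(a, size = p$alpha2, prob = p$beta2 / (p$beta2 + E))
  q1 <- p$w * f1 / (p$w * f1 + (1 - p$w) * f2)
  exp(q1 * (digamma(p$alpha1 + a) - log(p$beta1 + E)) +
        (1 - q1) * (digamma(p$alpha2 + a) - log(p$beta2 + E)))
}

# table with prescribed a and expected count E = (a+c)(a+b)/N
table_with_E <- function(a, E, ab = 1000, n = 1e6) {
  ac <- E * n / ab
  contingency_table(a, ab - a, ac - a, n - ab - (ac - a))
}

test_that("degenerate single-gamma prior reproduces the digamma closed form", {
  # identical components make the mixture a single Gamma(1, 1) prior
  p <- gps_prior(1, 1, 1, 1, 0.5)
  for (a in 0:50) {
    t <- table_with_E(a, 10)
    expect_equal(expected_count(t), 10, tolerance = 1e-12)
    v <- compute_mgps_ebgm(t, p)
    expect_equal(v[["estimate"]], exp(digamma(1 + a) - log(1 + 10)),
                 tolerance = 1e-10)
    # quantiles against the exact single-gamma quantile function
    expect_equal(v[["ci_low"]], qgamma(0.05, 1 + a, rate = 11),
                 tolerance = 1e-6)
    expect_equal(v[["ci_high"]], qgamma(0.95, 1 + a, rate = 11),
                 tolerance = 1e-6)
  }
})

test_that("posterior concentrates on a/E for large counts", {
  p <- gps_prior(0.2, 0.1, 2, 4, 1 / 3)
  v <- compute_mgps_ebgm(table_with_E(1000, 100, ab = 10000, n = 1e7), p)
  expect_lt(abs(v[["estimate"]] / 10 - 1), 0.02)
})

test_that("prior fitted on data from a known prior recovers its EBGM functionals", {
  set.seed(2024)
  true <- gps_prior(0.2, 0.1, 2, 4, 1 / 3)
  n <- 50000
  E <- exp(runif(n, log(0.1), log(100)))
  comp <- runif(n) < true$w
  lam <- ifelse(comp, rgamma(n, 0.2, rate = 0.1), rgamma(n, 2, rate = 4))
  a <- rpois(n, lam * E)
  fit <- fit_gps_prior(data.frame(a = a, E = E))

  probe <- expand.grid(a = c(1, 3, 10, 50, 200, 1000),
                       E = c(0.5, 2, 10, 100))
  rel <- mapply(function(a, E)
    abs(ebgm_closed_form(a, E, fit) / ebgm_closed_form(a, E, true) - 1),
    probe$a, probe$E)
  expect_lt(max(rel), 0.05)
  # fit is invariant to cell ordering
  perm <- sample(n)
  fit2 <- fit_gps_prior(data.frame(a = a[perm], E = E[perm]))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
})

test_that("null cells with a = E and large counts imply EBGM near 1", {
  E <- seq(100, 1090, by = 10)
  fit <- fit_gps_prior(data.frame(a = E, E = E))
  eb <- vapply(seq_along(E), function(i)
    compute_mgps_ebgm(table_with_E(E[i], E[i], ab = 10 * E[i], n = 1e7),
                      fit)[["estimate"]], numeric(1))
  expect_true(all(abs(eb - 1) < 0.05))
})

test_that("the shrinker always pulls estimates toward 1 under a null-fitted prior", {
  set.seed(31)
  n <- 2000
  E <- exp(rnorm(n, 1.5, 1))
  a <- rpois(n, E)                 # pure null: lambda = 1 everywhere
  fit <- fit_gps_prior(data.frame(a = a, E = E))
  # the fitted prior centres at its own geometric mean, which converges to
  # 1 under the null but carries finite-sample offset; shrinkage moves
  # every cell from its raw ratio toward that centre, never beyond
  gm_off <- abs(fit$w * (digamma(fit$alpha1) - log(fit$beta1)) +
                  (1 - fit$w) * (digamma(fit$alpha2) - log(fit$beta2)))

  set.seed(99)
  viol_mag <- viol_dir <- 0
  for (i in 1:1000) {
    aa <- sample(1:60, 1)
    t <- table_with_E(aa, exp(runif(1, log(0.5), log(50))),
                      ab = sample(500:5000, 1), n = 1e6)
    rr <- compute_rr_ebgm(t)[["estimate"]]
    mg <- compute_mgps_ebgm(t, fit)[["estimate"]]
    if (is.na(rr)) next
    if (abs(log(mg)) > abs(log(rr)) + gm_off + 1e-9)
      viol_mag <- viol_mag + 1
    if (aa > expected_count(t) && mg >= rr) viol_dir <- viol_dir + 1
  }
  expect_equal(viol_mag, 0)
  expect_equal(viol_dir, 0)   # a > E: the shrunk value sits below the ratio
})

test_that("MGPS screening shrinks small-count terms relative to the raw ratio", {
  gen <- generate_database(small_config(n = 4000, seed = 47))
  db <- clean_reports(gen$db)$db
  prior <- gps_prior(0.2, 0.1, 2, 4, 1 / 3)
  rr <- screen_signals(db, "esketamine")$stats
  mg <- screen_signals(db, "esketamine", ebgm_mode = "mgps",
                       prior = prior)$stats
  expect_equal(rr$term, mg$term)
  small <- which(rr$n <= 5 & rr$ebgm > 1)
  expect_true(all(mg$ebgm[small] < rr$ebgm[small]))
  # both modes respect the CI-bracketing invariant
  ok <- !is.na(mg$ebgm05)
  expect_true(all(mg$ebgm05[ok] <= mg$ebgm[ok] &
                    mg$ebgm[ok] <= mg$ebgm95[ok]))
})

test_that("the fit refuses too-small cell sets and reports convergence failures", {
  expect_error(fit_gps_prior(data.frame(a = 1:10, E = rep(1, 10))),
               "at least 50")
})
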