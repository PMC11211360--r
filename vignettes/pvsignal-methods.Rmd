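---
title: "Disproportionality methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems such as FAERS hold case reports submitted
without any exposure denominator, so absolute risks cannot be estimated.
Disproportionality analysis instead asks, for a target drug and each
adverse event term, whether the pair is reported more often than the
rest of the database predicts under independence. All statistics in this
package are functions of the four-grid table — `a` target-drug reports
with the event, `b` target-drug reports with other events, `c` and `d`
the same cells for all other drugs — built at either the preferred-term
(PT) or system-organ-class (SOC) level of the MedDRA hierarchy.

## Counting units

The package supports two counting units because published descriptive
tables genuinely mix them. With `counting_unit = "event_record"` (the
default) each distinct case–term pair is one countable record; per-SOC
record counts then sum to the total adverse-event record count, which is
how SOC-level percentage tables are normalised (e.g. 14,606 records over
6,887 cases in the esketamine profile this package's fixtures mirror).
With `counting_unit = "case"` each case counts exactly once, the
denominator used by demographic tables. Identical PTs within one case
are collapsed before counting, and SOC-level tables are built from
case–SOC pairs directly rather than by summing PT tables, so a case
holding several PTs of one SOC is not double-counted.

## Estimators

For a table with all cells positive:

* ROR \(= ad/bc\), CI \(\exp(\ln \mathrm{ROR} \pm z\sqrt{1/a+1/b+1/c+1/d})\) (Woolf).
* PRR \(= \frac{a/(a+b)}{c/(c+d)}\), CI \(\exp(\ln \mathrm{PRR} \pm z\sqrt{1/a-1/(a+b)+1/c-1/(c+d)})\).
* Relative reporting ratio RR \(= aN/((a+c)(a+b))\) — the
  observed-over-expected ratio. Spreadsheet pharmacovigilance practice
  prints this unshrunk ratio under the label EBGM and its lower Woolf
  bound as EBGM05; `ebgm_mode = "rr"` reproduces that convention.
* MGPS (`ebgm_mode = "mgps"`): \(a \sim \mathrm{Poisson}(\lambda E)\)
  with \(E=(a+c)(a+b)/N\) and
  \(\lambda \sim w\,\Gamma(\alpha_1,\beta_1) + (1-w)\,\Gamma(\alpha_2,\beta_2)\).
  The five prior parameters are fitted by maximising the
  negative-binomial mixture marginal over all (a, E) cells; the
  posterior is again a gamma mixture and
  \(\mathrm{EBGM} = \exp(E[\ln\lambda \mid a, E])\) is evaluated with
  the digamma function, with EB05/EB95 found by bisection on the
  mixture CDF to an interval tolerance of 1e-8.
* Pearson \(\chi^2\), Yates-corrected by default:
  \(N(|ad-bc|-N/2)^2 / ((a+b)(c+d)(a+c)(b+d))\). No χ² variant is
  canonical in this literature; the corrected form is the usual
  companion of the PRR, and the uncorrected form is available via
  `yates = FALSE`. Neither enters the default screening decision.

Why both EBGM modes: reports in the field frequently label the unshrunk
RR as "EBGM" (its values sit between PRR and 1, visibly shrunk relative
to ROR, which invites the confusion), while the estimator DuMouchel
defined is the empirical-Bayes posterior mean. The default is the RR
convention so that printed tables can be reproduced; `"mgps"` provides
the statistically principled shrinker, which matters for cells with
small `a` where the RR is noisy.

**Numerical choices.** A zero cell leaves a statistic undefined — its
screening flag then fails — because no continuity correction is part of
the conventional formulas; Haldane's +0.5 is available explicitly
(`zero_correction = "haldane"`). `z` is fixed at 1.96 for the default
95% level rather than `qnorm(0.975)` to match how the printed intervals
are computed; other confidence levels use the exact normal quantile.
The MGPS fit runs BFGS from a fixed six-point grid of starting values on
log/logit-transformed parameters, making it deterministic and invariant
to cell order; if no start converges, the error carries the best-so-far
parameters. Quantile bisection brackets with the two component
quantiles.

## Screening thresholds

The default `signal_criteria()` is the conventional multi-method screen:
`a ≥ 3` with the ROR 95% lower limit above 1, the same for PRR, and
EBGM05 > 2, combined as a conjunction (`combine = "all"`); `"any"`
gives the union reading. No multiplicity adjustment is applied by
default, matching standard practice in this literature where the screen
is a triage device rather than a hypothesis test; a Benjamini–Hochberg
column can be added downstream from the returned p-value-free flags if
desired (out of scope here).

## Cleaning rules

Reports dated strictly before the cutoff (default 2019-03-05, the
target drug's approval date) are removed; the comparison uses the event
date and falls back to the first day of the received year when the
event date is missing, because public exports often carry only
year-level receipt information. Reports with no coded reactions are
dropped as uninformative and counted separately in the cleaning report.
Deduplication is two-stage: (1) among reports sharing a case
identifier, only the highest version survives — FAERS resubmissions
supersede; (2) distinct case identifiers identical on the tuple (sex,
age group, country, event date, sorted PT multiset, seriousness) are
collapsed to the most recently received, the fingerprint of one episode
reported through two routes. Stage 2 can be disabled
(`dedup_mode = "version"`) since published analyses rarely state their
exact rule; both interpretations are runnable. All ties break
deterministically (smallest case id, then report id), so cleaning is
invariant to input row order.

## The synthetic generator

`generator_config()` defines a fully seeded generative model: drug
presence by per-drug marginals conditioned on at least one drug per
report (by redraw), primary-suspect role per present drug, PT inclusion
by per-term marginals conditioned on at least one reaction, implanted
(drug, PT) associations that multiply the term's inclusion probability
by a rate ratio (capped at 1; the ledger stores the effective post-cap
ratio) when the drug is present as primary suspect, independent
categorical demographics, a deterministic count of pre-cutoff-dated
reports, and duplicate contamination by cloning post-cutoff reports
under fresh case identifiers with identical deduplication tuples.

Two deliberate constructions keep validation exact. First,
`expected_contingency()` evaluates the closed-form expected cells by
enumerating the primary-suspect pattern of the implant-carrying drugs
and applying the same conditional-on-nonempty inclusion probabilities
the sampler uses — so expectation checks are exact, not approximations;
under an implant-free configuration the expected-cell ROR is exactly 1.
Second, before clones are injected the generator resolves any
accidental dedup-tuple collision among originals by deterministic
one-day date shifts, so running the real pipeline removes exactly the
ledger-listed duplicate and pre-cutoff records — an equality, not a
bound.

The defaults are the package's reference study conditions: 10,000
reports, a target drug present in ~2.8% of reports (primary suspect
with probability 0.8) against nine common psychotropic background
drugs, fifty PTs with marginals from 0.002 to 0.08, five
dissociation/sedation-spectrum terms implanted at rate ratio 20 on a
0.005 base rate (closed-form expected target-event count ≈ 31 after
cleaning), 5% duplicates, 5% pre-cutoff reports, and demographics
shaped like the published esketamine margins (53% female, ~80% US,
~79% healthcare-professional reporters, ~60% serious). What the
generator does **not** emulate: drug co-prescription correlation,
verbatim free-text reaction terms, reporting trends within years, or
demographically structured event rates. Passing tests therefore
demonstrate correctness of the pipeline and estimators under a clean
independence-plus-implants model, not robustness to the confounding and
stimulated-reporting artefacts of real spontaneous data.

## Published-margin fixtures

Exact reproduction of published FAERS-derived signal tables is not
possible at package scale — it requires the full multi-million-report
database, and printed (n, ROR, PRR, EBGM) triples in such tables are
often not jointly consistent with any single counting unit. What can be
checked is arithmetic: `esketamine_margins_db()` reconstructs a
6,887-case database whose marginal counts equal the published
demographic table and whose 14,606 reaction records distribute over the
25 SOCs exactly as the published SOC table, so
`demographics_summary()` and `soc_summary()` must reproduce every
printed percentage (53.03% female, 33.20% psychiatric, 16.67% nervous
system, 60.42% serious, 79.77% US, 78.82% healthcare professional).
Only the margins of that fixture are meaningful; its joint layout is an
arbitrary deterministic arrangement, and its filename and documentation
label it synthetic. Percentages round half-up to two decimals, matching
how the printed tables were formatted. The bundled PT→SOC table is a
miniature mapping in MedDRA's shape covering the terms the package
uses; it is not the licensed dictionary.

## Problem sizes used in validation

The shipped tests and acceptance script use: 2,000 multinomial draws at
N = 20,000 for interval coverage; 50 generator seeds at 10,000 reports
for detection power and false-flag rate; a 50,000-cell simulation for
MGPS prior recovery (probe-grid EBGM functionals within 5%); 1,000
random tables for the shrinkage property; and databases of 400–10,000
reports for pipeline properties. These sizes give the Monte-Carlo
resolution the asserted tolerances need (e.g. ±1.5% on 95% coverage)
while keeping a full run in minutes on one core.

## Known limitations

* The two-stage dedup rule is one reasonable codification of practice;
  real studies vary, which is why the version-only mode exists.
* MGPS is fitted on the target drug's own event terms when used inside
  `screen_signals()`; classical MGPS fits the full drug–event matrix.
  Supply a pre-fitted `gps_prior` for that behaviour.
* The RR-labelled EBGM mode reproduces reporting convention, not
  DuMouchel's estimator; the two disagree most where `a` is small —
  exactly where shrinkage matters.
* Stratified (age/sex/year) tables, Bayesian IC/BCPNN, regression-based
  signal detection and time-to-onset analyses are out of scope.
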