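Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on FAERS-style
    spontaneous adverse event report databases. Reads FDA Adverse Event
    Reporting System (FAERS) quarterly ASCII extracts and Public Dashboard
    style CSV exports, cleans and de-duplicates case reports, builds per-event
    2x2 contingency tables for a target drug, and computes the classical
    disproportionality statistics: reporting odds ratio (ROR), proportional
    reporting ratio (PRR), the relative reporting ratio commonly printed as
    EBGM, a DuMouchel-style multi-item gamma Poisson shrinker (MGPS) with
    empirical-Bayes EBGM/EB05, and Pearson chi-squared, each with 95%
    confidence intervals and configurable screening thresholds. Includes
    MedDRA preferred-term to system-organ-class aggregation, demographic and
    SOC-level summary tables, and a fully parameterised synthetic
    spontaneous-report generator with a ground-truth ledger for validating
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
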