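# In-code fixtures shared across test files.

# Minimal report constructor with sensible defaults
mk_report <- function(id, case = id, version = 0L, sex = "female",
                      age = "18-64", country = "US",
                      reporter = "healthcare_professional",
                      year = 2021L, date = as.Date("2021-06-01"),
                      serious = "non_serious", outcomes = "") {
  data.frame(report_id = id, case_id = case, version = version, sex = sex,
             age_group = age, weight_kg = NA_real_, country = country,
             reporter_type = reporter, received_year = year,
             event_date = date, seriousness = serious,
             serious_outcomes = outcomes, stringsAsFactors = FALSE)
}

mk_drug <- function(id, ingredient, role = "primary_suspect",
                    product = NA_character_) {
  data.frame(report_id = id, active_ingredient = ingredient,
             product_name = product, role = role,
             reason_for_use = NA_character_, stringsAsFactors = FALSE)
}

mk_reac <- function(id, pts) {
  data.frame(report_id = id, pt = pts, soc = map_pt_to_soc(pts),
             stringsAsFactors = FALSE)
}

# Build a database from a list of report specs:
#   list(list(id=, drug=, role=, pts=, ...), ...)
mk_db <- function(specs) {
  reports <- do.call(rbind, lapply(specs, function(s)
    do.call(mk_report, s[intersect(names(s),
                                   names(formals(mk_report)))])))
  drugs <- do.call(rbind, lapply(specs, function(s)
    mk_drug(s$id, s$drug, if (is.null(s$role)) "primary_suspect" else s$role,
            if (is.null(s$product)) NA_character_ else s$product)))
  reactions <- do.call(rbind, lapply(specs, function(s) mk_reac(s$id, s$pts)))
  report_db(reports, drugs, reactions, provenance = "test fixture")
}

# The six-report toy database: two target reports with reaction sets
# {PT1, PT2} and {PT1}; four other-drug reports with {PT1}, {PT2}, {PT2},
# {PT3} -- seven reaction records in total.
toy_db <- function() {
  mk_db(list(
    list(id = "T1", drug = "esketamine", pts = c("PT1", "PT2")),
    list(id = "T2", drug = "esketamine", pts = "PT1"),
    list(id = "O1", drug = "fluoxetine", pts = "PT1"),
    list(id = "O2", drug = "fluoxetine", pts = "PT2"),
    list(id = "O3", drug = "sertraline", pts = "PT2"),
    list(id = "O4", drug = "sertraline", pts = "PT3")))
}

# Small generator config for fast property loops
small_config <- function(n = 2000, seed = 101, ...) {
  generator_config(n_reports = n, seed = seed, ...)
}

no_implant_signals <- function() {
  data.frame(ingredient = character(), pt = character(),
             rate_ratio = numeric(), stringsAsFactors = FALSE)
}
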