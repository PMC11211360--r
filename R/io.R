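# Readers for the two public shapes of FAERS data: the quarterly
# dollar-delimited ASCII tables (DEMO/DRUG/REAC/OUTC) and Public
# Dashboard style one-row-per-case CSV exports. Both produce the same
# report_db. Unparseable optional fields become "unknown"; rows are never
# dropped at load time.

read_text_table <- function(path, sep) {
  stopifnot(file.exists(path))
  args <- list(file = path, sep = sep, header = TRUE, quote = if (sep == ",") "\"" else "",
               comment.char = "", colClasses = "character", fill = TRUE,
               check.names = FALSE, stringsAsFactors = FALSE,
               na.strings = character())
  # FAERS files are nominally UTF-8 but older quarters carry latin-1 bytes
  out <- tryCatch(do.call(utils::read.table,
                          c(args, list(fileEncoding = "UTF-8"))),
                  error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(out))
    out <- do.call(utils::read.table, c(args, list(fileEncoding = "latin1")))
  names(out) <- tolower(trimws(names(out)))
  out
}

require_cols <- function(df, cols_any, file, what) {
  ok <- vapply(cols_any, function(alt) any(alt %in% names(df)), logical(1))
  if (!all(ok)) {
    missing <- vapply(cols_any[!ok], function(alt)
      paste(alt, collapse = " or "), character(1))
    stop("format error in ", file, ": missing mandatory column(s) ",
         paste(missing, collapse = "; "), " (", what, ")")
  }
}

first_col <- function(df, candidates) {
  hit <- candidates[candidates %in% names(df)]
  if (!length(hit)) return(NULL)
  df[[hit[1]]]
}

parse_sex <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("F", "FEMALE")] <- "female"
  out[x %in% c("M", "MALE")] <- "male"
  out
}

parse_reporter <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("MD", "PH", "RN", "OT", "HP", "HEALTHCARE PROFESSIONAL",
               "HEALTHCARE_PROFESSIONAL")] <- "healthcare_professional"
  out[x %in% c("CN", "CONSUMER")] <- "consumer"
  out
}

parse_role <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("concomitant", length(x))  # conservative default for odd codes
  out[x %in% c("PS", "PRIMARY_SUSPECT", "PRIMARY SUSPECT")] <- "primary_suspect"
  out[x %in% c("SS", "SECONDARY_SUSPECT", "SECONDARY SUSPECT")] <- "secondary_suspect"
  out[x %in% c("C", "CONCOMITANT")] <- "concomitant"
  out[x %in% c("I", "INTERACTING")] <- "interacting"
  out
}

OUTCOME_CODE_MAP <- c(DE = "death", LT = "life_threatening",
                      HO = "hospitalization", DS = "disability",
                      CA = "congenital_anomaly", OT = "other_serious",
                      RI = "other_serious")

parse_outcome_codes <- function(x) {
  x <- toupper(trimws(x))
  out <- unname(OUTCOME_CODE_MAP[x])
  # verbose dashboard labels
  out[is.na(out) & grepl("DIED|DEATH", x)] <- "death"
  out[is.na(out) & grepl("LIFE", x)] <- "life_threatening"
  out[is.na(out) & grepl("HOSPITAL", x)] <- "hospitalization"
  out[is.na(out) & grepl("DISAB", x)] <- "disability"
  out[is.na(out) & grepl("CONGENITAL", x)] <- "congenital_anomaly"
  out[is.na(out) & grepl("SERIOUS|REQUIRED", x)] <- "other_serious"
  lx <- tolower(x)
  out[is.na(out) & lx %in% OUTCOME_LEVELS] <- lx[is.na(out) & lx %in% OUTCOME_LEVELS]
  out[!is.na(out)]
}

# FAERS dates come as YYYYMMDD, YYYYMM or YYYY; anything else is NA
parse_faers_date <- function(x) {
  x <- gsub("[^0-9]", "", trimws(x))
  out <- rep(as.Date(NA), length(x))
  d8 <- nchar(x) == 8
  out[d8] <- as.Date(x[d8], format = "%Y%m%d")
  d6 <- nchar(x) == 6
  out[d6] <- as.Date(paste0(x[d6], "15"), format = "%Y%m%d")
  d4 <- nchar(x) == 4
  out[d4] <- as.Date(paste0(x[d4], "0701"), format = "%Y%m%d")
  out
}

parse_age_years <- function(age, code) {
  age <- suppressWarnings(as.numeric(age))
  code <- toupper(trimws(code))
  mult <- rep(1, length(age))
  mult[code == "DEC"] <- 10
  mult[code == "MON"] <- 1 / 12
  mult[code == "WK"] <- 1 / 52.18
  mult[code == "DY"] <- 1 / 365.25
  mult[code == "HR"] <- 1 / 8766
  age * mult
}

#' Load a FAERS quarterly ASCII extract
#'
#' Reads the dollar-delimited DEMO, DRUG, REAC and OUTC tables of a FAERS
#' quarterly release and joins them into one [report_db], one case report
#' per `primaryid`. Column headers are matched case-insensitively; fields
#' the tables do not carry (or carry unparseably) become `unknown`/`NA`
#' rather than causing rows to be dropped. A report is serious exactly when
#' at least one outcome row exists for it.
#'
#' @param demo_path,drug_path,reac_path,outc_path paths to the four
#'   dollar-delimited tables. `outc_path` may be `NULL` (all reports then
#'   load as non-serious).
#' @param mapping PT->SOC table used to annotate reaction records.
#' @return a `report_db`.
#' @export
load_faers_ascii <- function(demo_path, drug_path, reac_path,
                             outc_path = NULL,
                             mapping = default_pt_soc_map()) {
  demo <- read_text_table(demo_path, "$")
  drug <- read_text_table(drug_path, "$")
  reac <- read_text_table(reac_path, "$")
  outc <- if (!is.null(outc_path)) read_text_table(outc_path, "$") else NULL

  id_cols <- c("primaryid", "caseid")
  require_cols(demo, list(id_cols), basename(demo_path), "DEMO")
  require_cols(drug, list(id_cols, "role_cod", c("drugname", "prod_ai")),
               basename(drug_path), "DRUG")
  require_cols(reac, list(id_cols, "pt"), basename(reac_path), "REAC")
  if (!is.null(outc))
    require_cols(outc, list(id_cols, "outc_cod"), basename(outc_path), "OUTC")

  get_pid <- function(df) {
    pid <- first_col(df, "primaryid")
    if (is.null(pid)) pid <- first_col(df, "caseid")
    trimws(pid)
  }
  pid_demo <- get_pid(demo)
  pid_drug <- get_pid(drug)
  pid_reac <- get_pid(reac)
  pid_outc <- if (!is.null(outc)) get_pid(outc) else character()

  all_ids <- unique(c(pid_demo, pid_drug, pid_reac))
  if (!length(all_ids)) {
    warning("FAERS extract contains no data rows; returning empty database")
    return(empty_report_db(provenance = "faers_ascii (empty)"))
  }

  # primaryid encodes caseid + version; recover both when possible
  caseid <- first_col(demo, "caseid")
  caseversion <- first_col(demo, "caseversion")
  di <- match(all_ids, pid_demo)
  case_id <- all_ids
  version <- rep(0L, length(all_ids))
  if (!is.null(caseid)) {
    cid <- trimws(caseid)[di]
    has <- !is.na(cid) & nzchar(cid)
    case_id[has] <- cid[has]
    pref <- has & startsWith(all_ids, case_id) & nchar(all_ids) > nchar(case_id)
    suff <- substring(all_ids[pref], nchar(case_id[pref]) + 1L)
    version[pref] <- suppressWarnings(as.integer(suff))
  }
  if (!is.null(caseversion)) {
    v <- suppressWarnings(as.integer(trimws(caseversion)))[di]
    version[!is.na(v)] <- v[!is.na(v)]
  }
  version[is.na(version)] <- 0L

  grab <- function(cols) {
    v <- first_col(demo, cols)
    if (is.null(v)) rep(NA_character_, length(all_ids)) else trimws(v)[di]
  }
  sex <- parse_sex(grab(c("sex", "gndr_cod")))
  age_years <- parse_age_years(grab("age"), grab("age_cod"))
  wt <- suppressWarnings(as.numeric(grab("wt")))
  wt_cod <- toupper(grab("wt_cod"))
  wt[!is.na(wt_cod) & wt_cod %in% c("LBS", "LB")] <-
    wt[!is.na(wt_cod) & wt_cod %in% c("LBS", "LB")] * 0.4536
  wt[!is.na(wt) & wt <= 0] <- NA_real_
  country <- grab(c("reporter_country", "occr_country"))
  country[is.na(country) | !nzchar(country)] <- "unknown"
  reporter <- parse_reporter(grab("occp_cod"))
  event_date <- parse_faers_date(grab(c("event_dt")))
  recv <- parse_faers_date(grab(c("fda_dt", "init_fda_dt", "rept_dt")))
  received_year <- as.integer(format(recv, "%Y"))
  fallback <- is.na(received_year) & !is.na(event_date)
  received_year[fallback] <- as.integer(format(event_date[fallback], "%Y"))

  outcomes <- rep("", length(all_ids))
  if (!is.null(outc) && nrow(outc)) {
    codes <- split(trimws(outc$outc_cod), pid_outc)
    parsed <- vapply(codes, function(v)
      paste(sort(unique(parse_outcome_codes(v))), collapse = ";"),
      character(1))
    oi <- match(all_ids, names(parsed))
    outcomes[!is.na(oi)] <- unname(parsed[oi[!is.na(oi)]])
  }
  seriousness <- ifelse(nzchar(outcomes), "serious", "non_serious")

  reports <- data.frame(report_id = all_ids, case_id = case_id,
                        version = version, sex = sex,
                        age_group = age_to_group(age_years),
                        weight_kg = wt, country = country,
                        reporter_type = reporter,
                        received_year = received_year,
                        event_date = event_date,
                        seriousness = seriousness,
                        serious_outcomes = outcomes,
                        stringsAsFactors = FALSE)

  ai <- first_col(drug, "prod_ai")
  dn <- first_col(drug, "drugname")
  if (is.null(ai)) ai <- dn
  if (is.null(dn)) dn <- rep(NA_character_, nrow(drug))
  blank_ai <- is.na(ai) | !nzchar(trimws(ai))
  ai[blank_ai] <- dn[blank_ai]
  reason <- first_col(drug, c("indi_pt", "reason_for_use"))
  if (is.null(reason)) reason <- rep(NA_character_, nrow(drug))
  drugs <- data.frame(report_id = pid_drug,
                      active_ingredient = trimws(ai),
                      product_name = trimws(dn),
                      role = parse_role(drug$role_cod),
                      reason_for_use = reason,
                      stringsAsFactors = FALSE)
  drugs <- drugs[!is.na(drugs$active_ingredient) &
                   nzchar(drugs$active_ingredient), , drop = FALSE]

  reactions <- data.frame(report_id = pid_reac,
                          pt = trimws(reac$pt),
                          stringsAsFactors = FALSE)
  reactions <- reactions[nzchar(reactions$pt), , drop = FALSE]
  reactions$soc <- map_pt_to_soc(reactions$pt, mapping)

  report_db(reports, drugs, reactions,
            provenance = paste0("faers_ascii:", basename(demo_path)))
}

#' Default dashboard column mapping
#'
#' Internal field names mapped to the CSV headers used by Public Dashboard
#' style exports (and by [write_dashboard_csv()]). Override entries to read
#' an export with different headers.
#'
#' @return named character vector (internal field -> CSV header).
#' @export
dashboard_column_map <- function() {
  c(case_id = "Case ID",
    version = "Version",
    sex = "Sex",
    age = "Patient Age",
    age_group = "Age Group",
    weight_kg = "Patient Weight",
    country = "Country where Event occurred",
    reporter_type = "Reporter Type",
    received_year = "Year Received",
    event_date = "Event Date",
    seriousness = "Serious",
    serious_outcomes = "Outcomes",
    reactions = "Reactions",
    ingredients = "Suspect Product Active Ingredients",
    product_names = "Suspect Product Names",
    roles = "Drug Roles")
}

#' Load a dashboard-style CSV export
#'
#' Reads a one-row-per-case CSV in the style of the FAERS Public Dashboard.
#' Multi-valued cells (reactions, ingredients, product names, roles,
#' outcomes) are split on `;`. When the export carries no aligned `roles`
#' column, the first listed suspect ingredient is taken as the primary
#' suspect and the rest as secondary suspects, matching dashboard
#' convention. When no explicit version column exists, a trailing
#' `-<digits>` run in the case identifier is parsed as the version
#' (otherwise version 0).
#'
#' @param path CSV file path.
#' @param column_map named character vector as returned by
#'   [dashboard_column_map()]; entries may be dropped or renamed to match
#'   the export at hand.
#' @param mapping PT->SOC table used to annotate reaction records.
#' @return a `report_db`.
#' @export
load_dashboard_csv <- function(path, column_map = dashboard_column_map(),
                               mapping = default_pt_soc_map()) {
  df <- read_text_table(path, ",")
  hdr <- tolower(unname(column_map))
  names(hdr) <- names(column_map)
  pick <- function(field) {
    h <- hdr[field]
    if (is.na(h) || !(h %in% names(df))) return(NULL)
    df[[h]]
  }
  if (is.null(pick("case_id")))
    stop("format error in ", basename(path), ": missing mandatory column ",
         shQuote(unname(column_map["case_id"])))
  if (is.null(pick("reactions")))
    stop("format error in ", basename(path), ": missing mandatory column ",
         shQuote(unname(column_map["reactions"])))
  n <- nrow(df)
  if (!n) {
    warning("dashboard export contains no data rows; returning empty database")
    return(empty_report_db(provenance = paste0("dashboard_csv:",
                                               basename(path))))
  }

  raw_id <- trimws(pick("case_id"))
  vcol <- pick("version")
  if (!is.null(vcol)) {
    version <- suppressWarnings(as.integer(trimws(vcol)))
    case_id <- raw_id
  } else {
    m <- regmatches(raw_id, regexpr("-[0-9]+$", raw_id))
    version <- rep(0L, n)
    has <- grepl("-[0-9]+$", raw_id)
    version[has] <- as.integer(sub("^-", "", regmatches(raw_id,
                                regexpr("-[0-9]+$", raw_id))))
    case_id <- sub("-[0-9]+$", "", raw_id)
  }
  version[is.na(version)] <- 0L
  report_id <- paste0(case_id, ".", version)
  if (anyDuplicated(report_id))
    report_id <- make.unique(report_id, sep = "_r")

  sex <- parse_sex(opt_chr(pick("sex"), n))
  agecol <- pick("age")
  if (!is.null(agecol)) {
    age_group <- age_to_group(suppressWarnings(as.numeric(agecol)))
  } else {
    ag <- opt_chr(pick("age_group"), n)
    age_group <- ifelse(ag %in% AGE_LEVELS, ag, "unknown")
  }
  wt <- suppressWarnings(as.numeric(opt_chr(pick("weight_kg"), n)))
  wt[!is.na(wt) & wt <= 0] <- NA_real_
  country <- opt_chr(pick("country"), n)
  country[!nzchar(country)] <- "unknown"
  reporter <- parse_reporter(opt_chr(pick("reporter_type"), n))
  event_date <- as.Date(opt_chr(pick("event_date"), n),
                        format = "%Y-%m-%d")
  yr <- suppressWarnings(as.integer(opt_chr(pick("received_year"), n)))
  fallback <- is.na(yr) & !is.na(event_date)
  yr[fallback] <- as.integer(format(event_date[fallback], "%Y"))

  outcomes_raw <- opt_chr(pick("serious_outcomes"), n)
  outcomes <- vapply(strsplit(outcomes_raw, ";", fixed = TRUE), function(v)
    paste(sort(unique(parse_outcome_codes(v))), collapse = ";"), character(1))
  ser_raw <- toupper(opt_chr(pick("seriousness"), n))
  seriousness <- ifelse(nzchar(outcomes) |
                          ser_raw %in% c("SERIOUS", "YES", "Y", "TRUE"),
                        "serious", "non_serious")
  outcomes[seriousness != "serious"] <- ""

  reports <- data.frame(report_id = report_id, case_id = case_id,
                        version = version, sex = sex, age_group = age_group,
                        weight_kg = wt, country = country,
                        reporter_type = reporter, received_year = yr,
                        event_date = event_date, seriousness = seriousness,
                        serious_outcomes = outcomes, stringsAsFactors = FALSE)

  split_cells <- function(x) lapply(strsplit(opt_chr(x, n), ";", fixed = TRUE),
                                    function(v) trimws(v[nzchar(trimws(v))]))
  pts <- split_cells(pick("reactions"))
  reactions <- data.frame(
    report_id = rep(report_id, lengths(pts)),
    pt = unlist(pts, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!nrow(reactions)) reactions <- empty_reactions_df()
  else reactions$soc <- map_pt_to_soc(reactions$pt, mapping)

  ings <- split_cells(pick("ingredients"))
  prods <- lapply(strsplit(opt_chr(pick("product_names"), n), ";",
                           fixed = TRUE), trimws)
  roles <- lapply(strsplit(opt_chr(pick("roles"), n), ";", fixed = TRUE),
                  trimws)
  drows <- lapply(seq_len(n), function(i) {
    ing <- ings[[i]]
    if (!length(ing)) return(NULL)
    k <- length(ing)
    pn <- prods[[i]]
    pn <- if (length(pn) == k) pn else rep(NA_character_, k)
    pn[!is.na(pn) & !nzchar(pn)] <- NA_character_
    rl <- roles[[i]]
    rl <- if (length(rl) == k) parse_role(rl)
          else c("primary_suspect", rep("secondary_suspect", k - 1L))
    data.frame(report_id = report_id[i], active_ingredient = ing,
               product_name = pn, role = rl,
               reason_for_use = NA_character_, stringsAsFactors = FALSE)
  })
  drugs <- do.call(rbind, c(list(empty_drugs_df()), drows))

  report_db(reports, drugs, reactions,
            provenance = paste0("dashboard_csv:", basename(path)))
}

opt_chr <- function(x, n) {
  if (is.null(x)) rep("", n) else {
    x <- trimws(as.character(x)); x[is.na(x)] <- ""; x
  }
}

#' Write a database as a dashboard-style CSV
#'
#' Serialises a `report_db` to the one-row-per-case CSV layout read by
#' [load_dashboard_csv()] with its default column map. Reactions, drug
#' ingredients, product names and role codes are `;`-joined; the aligned
#' `Drug Roles` column makes the round trip lossless for every field used
#' by the analysis.
#'
#' @param db a `report_db`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dashboard_csv <- function(db, path) {
  r <- db$reports
  join_by_report <- function(tbl, col) {
    if (!nrow(tbl)) return(rep("", nrow(r)))
    sp <- split(tbl[[col]], tbl$report_id)
    out <- vapply(sp, function(v) {
      v <- as.character(v); v[is.na(v)] <- ""
      paste(v, collapse = ";")
    }, character(1))
    idx <- match(r$report_id, names(out))
    ifelse(is.na(idx), "", out[idx])
  }
  role_abbr <- c(primary_suspect = "PS", secondary_suspect = "SS",
                 concomitant = "C", interacting = "I")
  drugs <- db$drugs
  drugs$role_code <- unname(role_abbr[drugs$role])
  out <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    `Case ID` = r$case_id,
    `Version` = r$version,
    `Sex` = r$sex,
    `Age Group` = r$age_group,
    `Patient Weight` = r$weight_kg,
    `Country where Event occurred` = r$country,
    `Reporter Type` = r$reporter_type,
    `Year Received` = r$received_year,
    `Event Date` = ifelse(is.na(r$event_date), "",
                          format(r$event_date, "%Y-%m-%d")),
    `Serious` = ifelse(r$seriousness == "serious", "Serious", "Non-Serious"),
    `Outcomes` = r$serious_outcomes,
    `Reactions` = join_by_report(db$reactions, "pt"),
    `Suspect Product Active Ingredients` = join_by_report(drugs,
                                                          "active_ingredient"),
    `Suspect Product Names` = join_by_report(drugs, "product_name"),
    `Drug Roles` = join_by_report(drugs, "role_code"))
  # distinct versions of one case must stay distinct rows
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
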