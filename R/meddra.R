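# PT -> SOC aggregation. A miniature mapping ships with the package; users
# with a licensed MedDRA distribution can supply their own two-column table.

.pv_env <- new.env(parent = emptyenv())

#' Bundled preferred-term to system-organ-class mapping
#'
#' Returns the miniature MedDRA-style mapping shipped with the package: a
#' two-column data.frame (`pt`, `soc`) covering the preferred terms used by
#' the synthetic generator and the esketamine worked examples. It is a small
#' excerpt in MedDRA's shape, not the licensed dictionary.
#'
#' @return data.frame with columns `pt` and `soc`.
#' @export
default_pt_soc_map <- function() {
  if (is.null(.pv_env$pt_soc_map)) {
    path <- system.file("extdata", "pt_soc_map.csv", package = "pvsignal",
                        mustWork = TRUE)
    .pv_env$pt_soc_map <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .pv_env$pt_soc_map
}

#' Map preferred terms to system organ classes
#'
#' Looks each PT up in a PT->SOC table. Terms absent from the mapping get
#' the sentinel class `"Unmapped"` rather than an error, so an incomplete
#' dictionary never drops reaction records.
#'
#' @param pt character vector of MedDRA preferred terms.
#' @param mapping two-column data.frame (`pt`, `soc`); defaults to the
#'   bundled mapping.
#' @return character vector of SOC labels, same length as `pt`.
#' @export
map_pt_to_soc <- function(pt, mapping = default_pt_soc_map()) {
  idx <- match(pt, mapping$pt)
  out <- mapping$soc[idx]
  out[is.na(idx)] <- "Unmapped"
  out
}

#' Recompute the SOC of every reaction record
#'
#' Overwrites the `soc` column of the reaction table with the mapping's
#' value for each PT, restoring the invariant that `soc` always equals
#' `map_pt_to_soc(pt)`.
#'
#' @param db a `report_db`.
#' @param mapping PT->SOC table as in [map_pt_to_soc()].
#' @return the database with refreshed SOC labels.
#' @export
apply_soc_mapping <- function(db, mapping = default_pt_soc_map()) {
  db$reactions$soc <- map_pt_to_soc(db$reactions$pt, mapping)
  db
}
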