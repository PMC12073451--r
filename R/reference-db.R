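#' Load the packaged CE-ESI-MS reference metabolite database
#'
#' The package ships a 50-entry in-house-style CE-ESI-MS reference database
#' of small polar metabolites: name, elemental formula, adduct type
#' (protonated molecule or intrinsic cation), measured and theoretical m/z,
#' reference migration time (min), and two confidence flags in the style of
#' the Metabolomics Standards Initiative: `mtmz_match` (accurate m/z plus
#' migration-time match) and `msms_support` (identification additionally
#' supported by MS/MS in the source database; the pipeline treats this as a
#' boolean provenance flag and performs no spectral scoring).
#'
#' On load the theoretical m/z column is revalidated against the stored
#' elemental formulas via [theoretical_mz()]; a mismatch beyond the printed
#' 4-decimal precision aborts, so a corrupted file cannot propagate.
#'
#' @param path Path to a TSV with the same schema; defaults to the packaged
#'   database.
#' @return A data.frame with 50 rows and columns `name`, `formula`, `adduct`,
#'   `mz_measured`, `mz_theoretical`, `ref_mt_min`, `delta_mt_pct`,
#'   `delta_printed`, `mtmz_match`, `msms_support`.
#' @examples
#' db <- load_packaged_reference()
#' nrow(db)  # 50
#' @export
load_packaged_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_db.tsv", package = "cemetab",
                        mustWork = TRUE)
  }
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "formula", "adduct", "mz_measured", "mz_theoretical",
                "ref_mt_min", "delta_mt_pct", "delta_printed",
                "mtmz_match", "msms_support")
  if (!all(required %in% names(db))) {
    stop("reference database is missing columns: ",
         paste(setdiff(required, names(db)), collapse = ", "), call. = FALSE)
  }
  if (anyNA(db[required])) stop("reference database contains NA", call. = FALSE)
  recomputed <- round_mz(mapply(theoretical_mz, db$formula, db$adduct))
  off <- abs(recomputed - db$mz_theoretical) > 5e-5
  if (any(off)) {
    stop("reference database corrupted: theoretical m/z does not reproduce ",
         "from formula for ", paste(db$name[off], collapse = ", "),
         call. = FALSE)
  }
  db$mtmz_match   <- as.logical(db$mtmz_match)
  db$msms_support <- as.logical(db$msms_support)
  db
}

#' Confidence flag of a reference entry
#'
#' Maps the two database booleans onto the reporting tiers used throughout
#' the pipeline: `"mt_mz_msms"` (double asterisk; MS/MS-supported),
#' `"mt_mz"` (single asterisk; m/z + migration-time match only).
#'
#' @param db Reference database data.frame.
#' @return Character vector of flags, one per entry.
#' @export
reference_flags <- function(db) {
  ifelse(db$msms_support, "mt_mz_msms", "mt_mz")
}
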