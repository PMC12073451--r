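#' Match calibrated features against the reference database
#'
#' A feature is identified when a reference lies within both tolerances:
#' absolute ppm deviation at most `ppm_tol` and migration-time deviation
#' (percent of the reference migration time) at most `mt_tol_pct`. Among
#' references passing both gates the one minimizing the combined normalized
#' distance `d = sqrt((dppm/ppm_tol)^2 + (dmt_pct/mt_tol_pct)^2)` is
#' assigned; ties on `d` break lexicographically by reference name, making
#' the assignment deterministic under any input ordering. One-to-one
#' matching is not enforced: a reference claimed by several features (e.g.
#' after peak splitting) is reported with `ambiguous = TRUE` rather than
#' silently dropped.
#'
#' @param features Calibrated, aligned feature data.frame (`mz`, `mt_min`).
#' @param refdb Reference database (non-empty).
#' @param ppm_tol m/z tolerance in ppm (default 3).
#' @param mt_tol_pct Migration-time tolerance in percent (default 3).
#' @return The feature data.frame with appended columns `ref_name`
#'   (`"unknown"` when unmatched), `dppm`, `dmt_pct`, `distance`, `flag`
#'   (`"mt_mz"`, `"mt_mz_msms"`, or `"unknown"`), `ambiguous`.
#' @export
match_features <- function(features, refdb, ppm_tol = 3, mt_tol_pct = 3) {
  if (is.null(refdb) || !nrow(refdb)) {
    stop("reference database is empty", call. = FALSE)
  }
  n <- nrow(features)
  ref_name <- rep("unknown", n)
  dppm <- rep(NA_real_, n)
  dmt <- rep(NA_real_, n)
  dist <- rep(NA_real_, n)
  flag <- rep("unknown", n)
  flags <- reference_flags(refdb)
  for (i in seq_len(n)) {
    dp <- ppm_deviation(features$mz[i], refdb$mz_theoretical)
    dm <- 100 * (features$mt_min[i] - refdb$ref_mt_min) / refdb$ref_mt_min
    ok <- abs(dp) <= ppm_tol & abs(dm) <= mt_tol_pct
    if (!any(ok)) next
    d <- sqrt((dp[ok] / ppm_tol)^2 + (dm[ok] / mt_tol_pct)^2)
    cand <- which(ok)[order(d, refdb$name[ok])]
    j <- cand[1]
    ref_name[i] <- refdb$name[j]
    dppm[i] <- dp[j]
    dmt[i] <- dm[j]
    dist[i] <- min(d)
    flag[i] <- flags[j]
  }
  out <- features
  out$ref_name <- ref_name
  out$dppm <- dppm
  out$dmt_pct <- dmt
  out$distance <- dist
  out$flag <- flag
  claimed <- table(ref_name[ref_name != "unknown"])
  out$ambiguous <- ref_name %in% names(claimed)[claimed > 1L]
  out
}

#' Summarize identification results
#'
#' @param matches Output of [match_features()].
#' @return list with `n_total`, `n_identified`, `n_mt_mz` (m/z +
#'   migration-time tier), `n_mt_mz_msms` (MS/MS-supported tier),
#'   `n_unknown`, `n_ambiguous`, and `identified_names`. The three tiers
#'   partition the feature list.
#' @export
summarize_identifications <- function(matches) {
  flag <- matches$flag
  list(
    n_total = length(flag),
    n_identified = sum(flag != "unknown"),
    n_mt_mz = sum(flag == "mt_mz"),
    n_mt_mz_msms = sum(flag == "mt_mz_msms"),
    n_unknown = sum(flag == "unknown"),
    n_ambiguous = sum(matches$ambiguous %||% FALSE),
    identified_names = sort(unique(matches$ref_name[flag != "unknown"]))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a match table to CSV
#'
#' Interchange columns: `run_id`, `mz`, `mt_aligned`, `ref_name`, `dppm`,
#' `dmt_pct`, `distance`, `flag`.
#'
#' @param matches Output of [match_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(matches, path) {
  out <- data.frame(run_id = matches$run_id, mz = matches$mz,
                    mt_aligned = matches$mt_min, ref_name = matches$ref_name,
                    dppm = matches$dppm, dmt_pct = matches$dmt_pct,
                    distance = matches$distance, flag = matches$flag)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
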