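#' Assemble the feature-by-sample abundance matrix
#'
#' Combines per-run matched feature tables into a quantitative matrix.
#' Identified features are keyed by reference name (when a run contributes
#' several records for one name, e.g. after peak splitting, their areas are
#' summed). Unknown features are clustered across runs by consensus m/z
#' (single-linkage, 3 ppm) and aligned migration time (3 percent); each
#' cluster becomes one row keyed by its consensus m/z and migration time.
#' Cells with no observation are imputed as half the smallest observed area
#' of that feature (standard below-detection convention); the imputation
#' count is recorded and observed cells are never altered.
#'
#' @param matches_list List (>= 2) of [match_features()] outputs, one per
#'   run; each must carry a single `run_id` present in `samples`.
#' @param samples data.frame with columns `sample` (matching run ids) and
#'   `group`.
#' @param ppm_tol,mt_tol_pct Unknown-clustering tolerances (defaults 3, 3).
#' @return An `abundance_matrix` object: list with `values` (features x
#'   samples), `mt_values` (aligned migration time per cell, NA where
#'   unobserved), `features` (data.frame `feature_id`, `kind`, `mz`, `mt_min`,
#'   `flag`), `samples`, `state = "raw"`, `n_imputed`.
#' @export
build_matrix <- function(matches_list, samples, ppm_tol = 3,
                         mt_tol_pct = 3) {
  if (length(matches_list) < 2L) {
    stop("need at least 2 runs to build an abundance matrix", call. = FALSE)
  }
  all_feats <- do.call(rbind, matches_list)
  if (!all(all_feats$run_id %in% samples$sample)) {
    stop("run ids missing from sample table", call. = FALSE)
  }
  sample_ids <- samples$sample

  iden <- all_feats[all_feats$ref_name != "unknown", , drop = FALSE]
  unk <- all_feats[all_feats$ref_name == "unknown", , drop = FALSE]

  rows <- list()
  if (nrow(iden)) {
    for (nm in sort(unique(iden$ref_name))) {
      sub <- iden[iden$ref_name == nm, , drop = FALSE]
      rows[[length(rows) + 1L]] <- list(
        feature_id = nm, kind = "identified",
        mz = stats::median(sub$mz), mt_min = stats::median(sub$mt_min),
        flag = sub$flag[1],
        area = tapply(sub$area, factor(sub$run_id, levels = sample_ids), sum),
        mt = tapply(sub$mt_min, factor(sub$run_id, levels = sample_ids),
                    stats::median)
      )
    }
  }
  if (nrow(unk)) {
    ord <- order(unk$mz, unk$mt_min)
    unk <- unk[ord, , drop = FALSE]
    gap <- diff(unk$mz) > ppm_tol * 1e-6 * unk$mz[-nrow(unk)]
    mz_cluster <- cumsum(c(1L, as.integer(gap)))
    for (cl in split(seq_len(nrow(unk)), mz_cluster)) {
      sub <- unk[cl, , drop = FALSE]
      sub <- sub[order(sub$mt_min), , drop = FALSE]
      mt_gap <- if (nrow(sub) > 1L) {
        diff(sub$mt_min) > mt_tol_pct / 100 * sub$mt_min[-nrow(sub)]
      } else logical(0)
      mt_cluster <- cumsum(c(1L, as.integer(mt_gap)))
      for (cl2 in split(seq_len(nrow(sub)), mt_cluster)) {
        ss <- sub[cl2, , drop = FALSE]
        cmz <- stats::median(ss$mz)
        cmt <- stats::median(ss$mt_min)
        rows[[length(rows) + 1L]] <- list(
          feature_id = sprintf("unk_%.4f@%.2f", cmz, cmt),
          kind = "unknown", mz = cmz, mt_min = cmt, flag = "unknown",
          area = tapply(ss$area, factor(ss$run_id, levels = sample_ids), sum),
          mt = tapply(ss$mt_min, factor(ss$run_id, levels = sample_ids),
                      stats::median)
        )
      }
    }
  }
  if (!length(rows)) stop("no features to assemble", call. = FALSE)

  values <- do.call(rbind, lapply(rows, function(r) as.numeric(r$area)))
  mt_values <- do.call(rbind, lapply(rows, function(r) as.numeric(r$mt)))
  feature_ids <- vapply(rows, `[[`, character(1), "feature_id")
  dimnames(values) <- list(feature_ids, sample_ids)
  dimnames(mt_values) <- list(feature_ids, sample_ids)

  n_imputed <- sum(is.na(values))
  for (i in seq_len(nrow(values))) {
    miss <- is.na(values[i, ])
    if (any(miss)) values[i, miss] <- min(values[i, !miss]) / 2
  }

  structure(list(
    values = values, mt_values = mt_values,
    features = data.frame(
      feature_id = feature_ids,
      kind = vapply(rows, `[[`, character(1), "kind"),
      mz = vapply(rows, `[[`, numeric(1), "mz"),
      mt_min = vapply(rows, `[[`, numeric(1), "mt_min"),
      flag = vapply(rows, `[[`, character(1), "flag"),
      stringsAsFactors = FALSE
    ),
    samples = samples, state = "raw", n_imputed = n_imputed
  ), class = "abundance_matrix")
}

#' Construct an abundance matrix from a plain area matrix
#'
#' Wraps a features-by-samples area matrix (e.g. planted areas from
#' [simulate_abundances()], or externally quantified data) into the
#' `abundance_matrix` container used by [qc_filter()] and [preprocess()].
#'
#' @param values Numeric matrix, features x samples, positive areas.
#' @param samples data.frame with `sample` and `group` columns matching the
#'   matrix columns.
#' @param features Optional feature annotation data.frame (defaults to the
#'   rownames).
#' @param mt_values Optional per-cell migration times (NA when absent).
#' @return An `abundance_matrix` in `raw` state.
#' @export
abundance_matrix <- function(values, samples, features = NULL,
                             mt_values = NULL) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == nrow(samples),
            all(c("sample", "group") %in% names(samples)))
  if (any(values < 0, na.rm = TRUE)) {
    stop("raw areas must be non-negative", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("feature_", seq_len(nrow(values)))
  }
  colnames(values) <- samples$sample
  if (is.null(features)) {
    features <- data.frame(feature_id = rownames(values),
                           stringsAsFactors = FALSE)
  }
  if (is.null(mt_values)) {
    mt_values <- matrix(NA_real_, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  }
  structure(list(values = values, mt_values = mt_values,
                 features = features, samples = samples, state = "raw",
                 n_imputed = 0L),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples; state:", x$state, "\n")
  cat("  groups:", paste(sprintf("%s(%d)", names(table(x$samples$group)),
                                 table(x$samples$group)), collapse = " "),
      "; imputed cells:", x$n_imputed, "\n")
  invisible(x)
}

rsd_pct <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}

#' Replicate quality control of an abundance matrix
#'
#' Computes, per feature and group, the relative standard deviation (RSD) of
#' the corrected migration time and of the quantified area over that group's
#' replicates, and gates them against the acceptance thresholds (default
#' < 5 percent MT RSD, < 25 percent area RSD; imputed cells are excluded). A
#' group with fewer than two observed values is recorded as not evaluable.
#' Failing features are flagged; with `drop = TRUE` they are removed from
#' the returned matrix.
#'
#' @param mat An `abundance_matrix` in `raw` state.
#' @param mt_rsd_max Migration-time RSD gate in percent (default 5).
#' @param area_rsd_max Area RSD gate in percent (default 25).
#' @param drop Remove failing features (default FALSE: flag only).
#' @return list with `matrix` (possibly filtered) and `report` (data.frame
#'   `feature_id`, `group`, `n_obs`, `mt_rsd`, `area_rsd`, `mt_pass`,
#'   `area_pass`, `evaluable`).
#' @export
qc_filter <- function(mat, mt_rsd_max = 5, area_rsd_max = 25, drop = FALSE) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (mat$state != "raw") stop("QC expects a raw matrix", call. = FALSE)
  groups <- unique(mat$samples$group)
  rep_rows <- list()
  for (i in seq_len(nrow(mat$values))) {
    observed <- !is.na(mat$mt_values[i, ])
    for (g in groups) {
      in_g <- mat$samples$group == g
      obs_g <- observed & in_g
      mt_rsd <- rsd_pct(mat$mt_values[i, obs_g])
      area_rsd <- rsd_pct(mat$values[i, obs_g])
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        feature_id = mat$features$feature_id[i], group = g,
        n_obs = sum(obs_g), mt_rsd = mt_rsd, area_rsd = area_rsd,
        mt_pass = is.na(mt_rsd) | mt_rsd < mt_rsd_max,
        area_pass = is.na(area_rsd) | area_rsd < area_rsd_max,
        evaluable = sum(obs_g) >= 2L,
        stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, rep_rows)
  fail_ids <- unique(report$feature_id[!(report$mt_pass & report$area_pass)])
  out <- mat
  if (drop && length(fail_ids)) {
    keep <- !(mat$features$feature_id %in% fail_ids)
    out$values <- out$values[keep, , drop = FALSE]
    out$mt_values <- out$mt_values[keep, , drop = FALSE]
    out$features <- out$features[keep, , drop = FALSE]
  }
  out$qc_failed <- fail_ids
  list(matrix = out, report = report)
}

#' Normalize, transform, and scale an abundance matrix
#'
#' Three-step preprocessing for multivariate analysis: (1) per-sample median
#' normalization — each sample column is multiplied by (reference median /
#' sample median), the reference being the median of sample medians, which
#' makes the normalization invariant to per-sample multiplicative scaling;
#' (2) log10 transform; (3) per-feature scaling across samples, either
#' autoscaling to mean 0 / sd 1 (default) or Pareto scaling (mean-centred,
#' divided by the square root of the sd). Features with zero variance map to
#' all-zero rows by convention. The state flag advances
#' raw -> normalized -> log10 -> scaled.
#'
#' @param mat An `abundance_matrix` (raw or QC-filtered).
#' @param scaling `"auto"` (default) or `"pareto"`.
#' @param stop_at Final state: `"scaled"` (default) or `"log10"` (skip the
#'   scaling step, e.g. when scaling is re-estimated within
#'   cross-validation folds).
#' @return The matrix in `scaled` (or `log10`) state.
#' @export
preprocess <- function(mat, scaling = c("auto", "pareto"),
                       stop_at = c("scaled", "log10")) {
  scaling <- match.arg(scaling)
  stop_at <- match.arg(stop_at)
  stopifnot(inherits(mat, "abundance_matrix"))
  if (mat$state != "raw") {
    stop("preprocess expects a raw matrix, got state '", mat$state, "'",
         call. = FALSE)
  }
  v <- mat$values
  med <- apply(v, 2, stats::median)
  if (any(med <= 0)) stop("zero or negative sample median", call. = FALSE)
  ref <- stats::median(med)
  v <- sweep(v, 2, ref / med, `*`)
  mat$state <- "normalized"
  if (any(v <= 0)) stop("non-positive values; cannot log-transform",
                        call. = FALSE)
  v <- log10(v)
  mat$state <- "log10"
  if (stop_at == "log10") {
    mat$values <- v
    return(mat)
  }
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  v <- v - mu
  const <- sdv == 0
  if (scaling == "auto") {
    v[!const, ] <- v[!const, , drop = FALSE] / sdv[!const]
  } else {
    v[!const, ] <- v[!const, , drop = FALSE] / sqrt(sdv[!const])
  }
  v[const, ] <- 0
  mat$values <- v
  mat$state <- "scaled"
  mat$scaling <- scaling
  mat
}

#' Write an abundance matrix as CSV with a two-row header
#'
#' First header row: sample ids; second row: group labels; then one row per
#' feature.
#'
#' @param mat An `abundance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(mat$values)), collapse = ","),
             con)
  writeLines(paste(c("group", mat$samples$group), collapse = ","), con)
  utils::write.table(
    data.frame(feature_id = rownames(mat$values), mat$values,
               check.names = FALSE),
    con, sep = ",", col.names = FALSE, row.names = FALSE, quote = TRUE
  )
  invisible(path)
}
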