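#' Pipeline configuration
#'
#' Collects every tunable of the processing chain with the study's defaults:
#' EIC extraction half-window 5 mDa, identification tolerances 3 ppm and 3
#' percent migration time, S/N gate 15, replicate QC gates 5 percent MT RSD
#' and 25 percent area RSD, third-order alignment, 10-fold cross-validation,
#' top-30 feature report, pathway significance p < 0.05.
#'
#' @param seed Master seed for the synthetic experiment.
#' @param eic_tol_mda EIC half-window (mDa).
#' @param ppm_tol,mt_tol_pct Identification tolerances.
#' @param sn_min S/N gate.
#' @param mt_rsd_max,area_rsd_max QC gates (percent).
#' @param align_order Migration-time alignment polynomial order.
#' @param cv_folds Cross-validation folds.
#' @param max_comp Largest component count evaluated in CV.
#' @param keepX sPLS-DA sparsity per component.
#' @param top_n Features reported by the influence ranking.
#' @param p_cutoff Pathway significance threshold.
#' @param noise Trace noise settings ([noise_spec()] or [noiseless()]).
#' @param noise_cv Abundance noise CV.
#' @param refdb_path Optional reference database TSV (default packaged).
#' @param pathway_path Optional pathway library JSON (default packaged demo).
#' @param out_dir Output directory for [run_pipeline()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, eic_tol_mda = 5, ppm_tol = 3,
                            mt_tol_pct = 3, sn_min = 15, mt_rsd_max = 5,
                            area_rsd_max = 25, align_order = 3L,
                            cv_folds = 10L, max_comp = 3L, keepX = 30L,
                            top_n = 30L, p_cutoff = 0.05,
                            noise = noise_spec(), noise_cv = 0.2,
                            refdb_path = NULL, pathway_path = NULL,
                            out_dir = tempfile("cemetab_run_")) {
  cfg <- list(seed = as.integer(seed), eic_tol_mda = eic_tol_mda,
              ppm_tol = ppm_tol, mt_tol_pct = mt_tol_pct, sn_min = sn_min,
              mt_rsd_max = mt_rsd_max, area_rsd_max = area_rsd_max,
              align_order = align_order, cv_folds = cv_folds,
              max_comp = max_comp, keepX = keepX, top_n = top_n,
              p_cutoff = p_cutoff, noise = noise, noise_cv = noise_cv,
              refdb_path = refdb_path, pathway_path = pathway_path,
              out_dir = out_dir)
  num <- c("eic_tol_mda", "ppm_tol", "mt_tol_pct", "sn_min", "mt_rsd_max",
           "area_rsd_max", "cv_folds", "top_n", "p_cutoff")
  if (any(unlist(cfg[num]) <= 0)) {
    stop("all tolerances and counts must be positive", call. = FALSE)
  }
  if (!is.null(refdb_path) && !file.exists(refdb_path)) {
    stop("reference database path does not exist: ", refdb_path,
         call. = FALSE)
  }
  if (!is.null(pathway_path) && !file.exists(pathway_path)) {
    stop("pathway library path does not exist: ", pathway_path,
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-experiment pipeline
#'
#' Executes simulate -> extract -> calibrate/align -> identify ->
#' quantify/QC -> preprocess -> sPLS-DA -> pathway analysis, writing every
#' stage's table plus a JSON manifest (config, seed, per-stage row counts)
#' into `config$out_dir`. Rerunning with the same seed reproduces all
#' outputs. Any stage failure halts with the stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @param design A [study_design()].
#' @param effects Planted effects (default [default_effects()]).
#' @return Invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         design = study_design(), effects = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  log_line("seed = ", config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  refdb <- stage("reference", load_packaged_reference(config$refdb_path))

  log_line("stage: simulate")
  expt <- stage("simulate", simulate_experiment(
    design, effects, seed = config$seed, noise = config$noise,
    noise_cv = config$noise_cv, refdb = refdb
  ))

  log_line("stage: extract + calibrate + identify")
  cal_mz <- calibrant_series(7L)$mz_theoretical
  matches_list <- vector("list", length(expt$runs))
  models <- vector("list", length(expt$runs))
  for (i in seq_along(expt$runs)) {
    run <- expt$runs[[i]]
    feats <- stage("extract", extract_features(
      run$trace, tol_mda = config$eic_tol_mda, sn_min = config$sn_min,
      exclude_mz = cal_mz
    ))
    cal <- stage("calibrate", calibrate_run(
      run$trace, feats, refdb, ppm_tol = config$ppm_tol,
      duration_min = design$duration_min
    ))
    models[[i]] <- cal$model
    matches_list[[i]] <- stage("identify", match_features(
      cal$features, refdb, ppm_tol = config$ppm_tol,
      mt_tol_pct = config$mt_tol_pct
    ))
    write_match_table(matches_list[[i]],
                      file.path(config$out_dir,
                                paste0("matches_", run$truth$run_id, ".csv")))
  }
  names(matches_list) <- expt$samples$sample

  log_line("stage: quantify")
  mat <- stage("quantify", build_matrix(matches_list, expt$samples,
                                        ppm_tol = config$ppm_tol,
                                        mt_tol_pct = config$mt_tol_pct))
  qc <- stage("qc", qc_filter(mat, config$mt_rsd_max, config$area_rsd_max))
  utils::write.csv(qc$report, file.path(config$out_dir, "qc_report.csv"),
                   row.names = FALSE)
  write_matrix_csv(mat, file.path(config$out_dir, "abundance_raw.csv"))

  log_line("stage: preprocess + splsda")
  scaled <- stage("preprocess", preprocess(qc$matrix))
  write_matrix_csv(scaled, file.path(config$out_dir, "abundance_scaled.csv"))
  X <- t(scaled$values)
  y <- scaled$samples$group
  cv <- stage("splsda", cross_validate(
    X, y, max_comp = config$max_comp, folds = config$cv_folds,
    keepX = config$keepX, seed = config$seed
  ))
  model <- stage("splsda", fit_splsda(X, y, ncomp = max(cv$chosen, 2L),
                                      keepX = config$keepX))
  ranked <- stage("splsda", rank_features(model, top_n = config$top_n))
  ranked$mz <- scaled$features$mz[match(ranked$feature,
                                        scaled$features$feature_id)]
  ranked$mt_min <- scaled$features$mt_min[match(ranked$feature,
                                                scaled$features$feature_id)]
  utils::write.csv(ranked, file.path(config$out_dir, "top_features.csv"),
                   row.names = FALSE)

  log_line("stage: pathway")
  lib <- stage("pathway", read_pathway_library(config$pathway_path))
  query <- ranked$feature[ranked$feature %in% refdb$name]
  pathways <- stage("pathway", analyze_pathways(query, lib,
                                                p_cutoff = config$p_cutoff))
  utils::write.csv(pathways, file.path(config$out_dir, "pathways.csv"),
                   row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "noise")],
    noise = config$noise,
    n_runs = length(expt$runs),
    features_per_run = vapply(matches_list, nrow, integer(1)),
    identified_per_run = vapply(matches_list, function(m) {
      sum(m$flag != "unknown")
    }, integer(1)),
    matrix_rows = nrow(mat$values),
    imputed_cells = mat$n_imputed,
    qc_failed = length(qc$matrix$qc_failed),
    cv_ber = as.list(cv$ber), chosen_ncomp = cv$chosen,
    top_features = ranked$feature,
    n_pathways_tested = nrow(pathways),
    n_pathways_significant = sum(pathways$significant),
    package_version = as.character(utils::packageVersion("cemetab")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("done: ", manifest$matrix_rows, " features x ",
           length(expt$runs), " runs")
  invisible(list(experiment = expt, matches = matches_list, models = models,
                 matrix = mat, qc = qc, scaled = scaled, cv = cv,
                 model = model, top_features = ranked, pathways = pathways,
                 manifest = manifest))
}

#' Ingest an externally produced peak list
#'
#' Reads a feature-table CSV (columns `run_id`, `mz`, `mt_min`, `area`,
#' `sn`), bypassing simulation and extraction. Malformed rows (non-positive
#' area, negative S/N, m/z outside 50-500) are rejected with their line
#' numbers.
#'
#' @param path CSV path.
#' @param mz_window Acceptable m/z window.
#' @return Validated feature data.frame.
#' @export
ingest_peaklist <- function(path, mz_window = c(50, 500)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "mz", "mt_min", "area", "sn")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("peak list is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) stop("peak list is empty", call. = FALSE)
  bad <- !is.finite(df$mz) | !is.finite(df$area) | !is.finite(df$sn) |
    df$area <= 0 | df$sn < 0 | df$mz < mz_window[1] | df$mz > mz_window[2]
  if (any(bad)) {
    stop("invalid peak list rows (line numbers incl. header): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a feature table as CSV
#'
#' @param features Feature data.frame (`run_id`, `mz`, `mt_min`, `area`,
#'   `sn`, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
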