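#' Study design for a synthetic CE-ESI-MS experiment
#'
#' Encodes the infection-study layout the generator emulates: three groups of
#' biological replicates (uninfected control `Ctrl`, symbiotic-nematode
#' infected `Sym`, axenic-nematode infected `Axe`), a run duration in
#' minutes, and the singly-charged detection window in m/z.
#'
#' @param n_ctrl,n_sym,n_axe Replicates per group (defaults 4, 4, 3).
#' @param duration_min Run duration (default 50 min).
#' @param mz_window Detection window, c(low, high) in Da (default 50-500).
#' @param scan_interval_min Centroided scan spacing (default 0.02 min).
#' @return A `study_design` list.
#' @export
study_design <- function(n_ctrl = 4L, n_sym = 4L, n_axe = 3L,
                         duration_min = 50, mz_window = c(50, 500),
                         scan_interval_min = 0.02) {
  stopifnot(n_ctrl >= 2L, n_sym >= 2L, n_axe >= 2L,
            length(mz_window) == 2L, mz_window[1] < mz_window[2],
            duration_min > 0, scan_interval_min > 0)
  groups <- c(rep("Ctrl", n_ctrl), rep("Sym", n_sym), rep("Axe", n_axe))
  samples <- data.frame(
    sample = paste0(groups, "_", c(seq_len(n_ctrl), seq_len(n_sym),
                                   seq_len(n_axe))),
    group = groups,
    stringsAsFactors = FALSE
  )
  structure(list(samples = samples, duration_min = duration_min,
                 mz_window = mz_window,
                 scan_interval_min = scan_interval_min),
            class = "study_design")
}

#' Default planted group effects
#'
#' The generator's default differential signal: +0.5 log10 units in the Sym
#' group for the nine symbiotic-enriched metabolites (pyridoxine, histidine,
#' carnitine, GABA, sarcosine, trolamine, lysine, choline, methylhistidine)
#' and +0.5 log10 units in the Axe group for the three axenic-enriched ones
#' (acetylhomoserine, homolysine, methylaspartate). All other features carry
#' no group effect.
#'
#' @return data.frame with columns `name`, `Ctrl`, `Sym`, `Axe` (log10
#'   abundance offsets).
#' @export
default_effects <- function() {
  sym <- c("Pyridoxine", "Histidine", "Carnitine", "Gamma-aminobutyrate",
           "Sarcosine", "Trolamine", "Lysine", "Choline", "Methylhistidine")
  axe <- c("Acetylhomoserine", "Homolysine", "Methylaspartate")
  data.frame(
    name = c(sym, axe),
    Ctrl = 0,
    Sym  = c(rep(0.5, length(sym)), rep(0, length(axe))),
    Axe  = c(rep(0, length(sym)), rep(0.5, length(axe))),
    stringsAsFactors = FALSE
  )
}

#' Per-run instrumental distortion
#'
#' Bundles the run-specific imperfections the pipeline must undo: a cubic
#' polynomial mapping true migration time to observed migration time
#' (`observed = c0 + c1 t + c2 t^2 + c3 t^3`, required monotone increasing
#' over the run), a global multiplicative m/z bias in ppm, and a
#' multiplicative abundance noise coefficient of variation.
#'
#' @param c0,c1,c2,c3 Polynomial coefficients (min).
#' @param ppm_bias Global m/z bias in ppm; |bias| must be <= 20.
#' @param noise_cv Abundance noise CV (fraction, default 0.2).
#' @param duration_min Run duration over which monotonicity is checked.
#' @return A `run_distortion` list.
#' @export
run_distortion <- function(c0 = 0, c1 = 1, c2 = 0, c3 = 0, ppm_bias = 0,
                           noise_cv = 0.2, duration_min = 50) {
  coefs <- c(c0, c1, c2, c3)
  stopifnot(is.finite(coefs), is.finite(ppm_bias), noise_cv >= 0)
  if (abs(ppm_bias) > 20) stop("|ppm_bias| must be <= 20", call. = FALSE)
  tt <- seq(0, duration_min, length.out = 512L)
  deriv <- c1 + 2 * c2 * tt + 3 * c3 * tt^2
  if (any(deriv <= 0)) {
    stop("migration-time distortion must be monotone increasing over the run",
         call. = FALSE)
  }
  structure(list(coefs = coefs, ppm_bias = ppm_bias, noise_cv = noise_cv,
                 duration_min = duration_min),
            class = "run_distortion")
}

#' Draw a random run distortion from the generator's prior
#'
#' Intercept uniform on \[-0.5, 0.5\] min, slope on \[0.95, 1.05\], small
#' quadratic and cubic terms constrained so the polynomial stays monotone;
#' ppm bias uniform on \[-10, 10\]. Uses the current RNG state.
#'
#' @param duration_min Run duration (min).
#' @param noise_cv Abundance noise CV.
#' @return A `run_distortion`.
#' @export
random_distortion <- function(duration_min = 50, noise_cv = 0.2) {
  for (i in 1:100) {
    cand <- try(run_distortion(
      c0 = stats::runif(1, -0.5, 0.5),
      c1 = stats::runif(1, 0.95, 1.05),
      c2 = stats::runif(1, -2e-4, 2e-4),
      c3 = stats::runif(1, -2e-6, 2e-6),
      ppm_bias = stats::runif(1, -10, 10),
      noise_cv = noise_cv, duration_min = duration_min
    ), silent = TRUE)
    if (!inherits(cand, "try-error")) return(cand)
  }
  stop("failed to draw a monotone distortion", call. = FALSE)
}

#' Apply a distortion polynomial to migration times
#'
#' @param distortion A `run_distortion`.
#' @param mt True migration times (min).
#' @return Observed (distorted) migration times.
#' @export
distort_mt <- function(distortion, mt) {
  cf <- distortion$coefs
  cf[1] + cf[2] * mt + cf[3] * mt^2 + cf[4] * mt^3
}

#' Theoretical sodium-formate calibrant series
#'
#' Cluster n has m/z = m(Na+) + n * m(NaHCO2); these clusters form in the
#' ion source and serve as internal m/z calibrants.
#'
#' @param n_max Largest cluster index (must be >= 3 for a usable series).
#' @param mz_window Optional window; clusters outside are dropped after the
#'   n_max >= 3 check.
#' @return data.frame with columns `n`, `mz_theoretical`.
#' @export
calibrant_series <- function(n_max = 7L, mz_window = NULL) {
  if (n_max < 3L) stop("need at least 3 calibrant clusters", call. = FALSE)
  k <- mass_constants()
  na_plus <- k$atomic[["Na"]] - k$electron
  naf <- k$atomic[["Na"]] + k$atomic[["H"]] + k$atomic[["C"]] +
    2 * k$atomic[["O"]]
  out <- data.frame(n = seq_len(n_max),
                    mz_theoretical = na_plus + seq_len(n_max) * naf)
  if (!is.null(mz_window)) {
    out <- out[out$mz_theoretical >= mz_window[1] &
                 out$mz_theoretical <= mz_window[2], , drop = FALSE]
  }
  out
}

#' Simulate an observed calibrant series under a ppm bias
#'
#' @param n_max Largest cluster index (>= 3).
#' @param ppm_bias Planted multiplicative m/z bias (ppm).
#' @param base_intensity Intensity of the n = 1 cluster; higher clusters
#'   decay as 1/n.
#' @return data.frame with columns `n`, `mz_theoretical`, `mz`, `intensity`.
#' @export
simulate_calibrant_series <- function(n_max = 7L, ppm_bias = 0,
                                      base_intensity = 3e4) {
  s <- calibrant_series(n_max)
  s$mz <- s$mz_theoretical * (1 + ppm_bias * 1e-6)
  s$intensity <- base_intensity / s$n
  s
}

#' Build the 122-feature panel for a synthetic experiment
#'
#' Fifty identifiable features are taken from the reference database at
#' their theoretical m/z and reference migration times; `n_unknown`
#' additional features are drawn uniformly in m/z over the detection window
#' (with a 0.01-Da exclusion zone around every reference m/z and a 0.025-Da
#' zone around calibrant clusters, so identity tests cannot collide) and in
#' migration time over 11-48 min. Peak widths (Gaussian sigma) are uniform
#' on 0.05-0.15 min; baseline log10 areas uniform on 4.7-5.7. Uses the
#' current RNG state.
#'
#' @param refdb Reference database (see [load_packaged_reference()]).
#' @param n_unknown Number of unidentifiable features (default 72).
#' @param mz_window Detection window.
#' @param unknown_mt_range Migration-time range for unknowns (min).
#' @return data.frame panel with one row per feature.
#' @export
make_feature_panel <- function(refdb, n_unknown = 72L,
                               mz_window = c(50, 500),
                               unknown_mt_range = c(11, 48)) {
  n_ref <- nrow(refdb)
  excl <- c(refdb$mz_theoretical, calibrant_series(7L)$mz_theoretical)
  excl_half <- c(rep(0.01, n_ref), rep(0.025, 7L))
  draw_unknown_mz <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      cand <- stats::runif(n, mz_window[1], mz_window[2])
      ok <- vapply(cand, function(m) all(abs(m - excl) > excl_half), logical(1))
      out <- c(out, cand[ok])
    }
    out[seq_len(n)]
  }
  unk_mz <- draw_unknown_mz(n_unknown)
  unk_mt <- stats::runif(n_unknown, unknown_mt_range[1], unknown_mt_range[2])
  panel <- data.frame(
    feature_id = c(paste0("ref_", refdb$name),
                   sprintf("unk_%03d", seq_len(n_unknown))),
    name = c(refdb$name, rep(NA_character_, n_unknown)),
    mz = c(refdb$mz_theoretical, unk_mz),
    mt = c(refdb$ref_mt_min, unk_mt),
    sigma = stats::runif(n_ref + n_unknown, 0.05, 0.15),
    base_log10_area = stats::runif(n_ref + n_unknown, 4.7, 5.7),
    stringsAsFactors = FALSE
  )
  panel
}

#' Trace-level noise settings
#'
#' @param baseline_rate Expected number of random baseline centroids per
#'   scan (Poisson; default 8). Zero disables baseline noise.
#' @param baseline_mean Mean intensity of baseline centroids (exponential;
#'   default 30 counts).
#' @param mz_jitter_ppm Per-centroid m/z jitter standard deviation in ppm
#'   (default 0.5).
#' @return A list of noise settings.
#' @export
noise_spec <- function(baseline_rate = 8, baseline_mean = 30,
                       mz_jitter_ppm = 0.5) {
  stopifnot(baseline_rate >= 0, baseline_mean > 0, mz_jitter_ppm >= 0)
  list(baseline_rate = baseline_rate, baseline_mean = baseline_mean,
       mz_jitter_ppm = mz_jitter_ppm)
}

#' Noise settings for a noiseless limit run
#' @return A `noise_spec` with every stochastic trace component disabled.
#' @export
noiseless <- function() noise_spec(baseline_rate = 0, baseline_mean = 1e-9,
                                   mz_jitter_ppm = 0)

resolve_effects <- function(effects, refdb) {
  if (is.null(effects)) return(default_effects())
  stopifnot(is.data.frame(effects),
            all(c("name", "Ctrl", "Sym", "Axe") %in% names(effects)))
  bad <- setdiff(effects$name, refdb$name)
  if (length(bad)) {
    stop("effect names not in reference database: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  effects
}

# log-normal multiplicative noise factor with unit mean and given CV
lnorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# planted per-sample areas for one run: base area x group effect x noise
sample_areas <- function(panel, group, effects, cv) {
  offset <- rep(0, nrow(panel))
  idx <- match(panel$name, effects$name)
  hit <- !is.na(idx)
  offset[hit] <- effects[[group]][idx[hit]]
  10^(panel$base_log10_area + offset) * lnorm_factor(nrow(panel), cv)
}

#' Simulate one CE-ESI-MS run
#'
#' Generates a centroided scan-level raw trace for one sample: each planted
#' feature appears as a Gaussian electrophoretic peak at its distorted
#' migration time and ppm-shifted m/z, with log-normal abundance noise
#' around the group mean; sodium-formate calibrant clusters appear in every
#' scan; random baseline centroids provide chemical noise. Centroids below
#' one count are dropped (detector quantization). Reproducible for a fixed
#' seed.
#'
#' @param design A [study_design()].
#' @param effects Planted group effects (default [default_effects()]).
#' @param distortion A [run_distortion()].
#' @param seed Integer seed for this run.
#' @param panel Feature panel from [make_feature_panel()]; if `NULL`, a
#'   panel is drawn under `seed` (per-experiment panels should be built once
#'   and shared across runs).
#' @param refdb Reference database.
#' @param group Group label of the sample (`"Ctrl"`, `"Sym"`, `"Axe"`).
#' @param run_id Run identifier written into the trace.
#' @param noise A [noise_spec()].
#' @param n_calibrant Largest calibrant cluster index.
#' @return list with `trace` (data.frame `run_id`, `scan`, `time_min`, `mz`,
#'   `intensity`) and `truth` (list: `features` data.frame with planted
#'   identities, m/z, migration times, areas, amplitudes; `distortion`;
#'   `group`).
#' @export
simulate_run <- function(design = study_design(), effects = NULL,
                         distortion = run_distortion(), seed,
                         panel = NULL, refdb = load_packaged_reference(),
                         group = "Ctrl", run_id = "run1",
                         noise = noise_spec(), n_calibrant = 7L) {
  if (missing(seed)) stop("seed must be supplied", call. = FALSE)
  stopifnot(inherits(distortion, "run_distortion"))
  effects <- resolve_effects(effects, refdb)
  set.seed(seed)
  if (is.null(panel)) panel <- make_feature_panel(refdb,
                                                  mz_window = design$mz_window)
  dur <- design$duration_min
  times <- seq(design$scan_interval_min, dur, by = design$scan_interval_min)
  n_scan <- length(times)

  areas <- sample_areas(panel, group, effects, distortion$noise_cv)
  amp <- areas / (panel$sigma * sqrt(2 * pi))
  mt_obs <- distort_mt(distortion, panel$mt)
  mz_obs <- panel$mz * (1 + distortion$ppm_bias * 1e-6)

  piece <- vector("list", nrow(panel) + 2L)
  for (i in seq_len(nrow(panel))) {
    lo <- max(1L, ceiling((mt_obs[i] - 4 * panel$sigma[i]) /
                            design$scan_interval_min))
    hi <- min(n_scan, floor((mt_obs[i] + 4 * panel$sigma[i]) /
                              design$scan_interval_min))
    if (lo > hi) next
    sc <- lo:hi
    inten <- amp[i] * exp(-(times[sc] - mt_obs[i])^2 / (2 * panel$sigma[i]^2))
    keep <- inten >= 1
    if (!any(keep)) next
    sc <- sc[keep]; inten <- inten[keep]
    mzv <- rep(mz_obs[i], length(sc))
    if (noise$mz_jitter_ppm > 0) {
      mzv <- mzv * (1 + stats::rnorm(length(sc)) * noise$mz_jitter_ppm * 1e-6)
    }
    piece[[i]] <- data.frame(scan = sc, mz = mzv, intensity = inten)
  }

  cal <- simulate_calibrant_series(n_calibrant, distortion$ppm_bias)
  cal <- cal[cal$mz_theoretical >= design$mz_window[1] &
               cal$mz_theoretical <= design$mz_window[2], , drop = FALSE]
  if (nrow(cal)) {
    sc <- rep(seq_len(n_scan), times = nrow(cal))
    mzv <- rep(cal$mz, each = n_scan)
    if (noise$mz_jitter_ppm > 0) {
      mzv <- mzv * (1 + stats::rnorm(length(mzv)) * noise$mz_jitter_ppm * 1e-6)
    }
    inten <- rep(cal$intensity, each = n_scan) *
      (1 + 0.05 * stats::rnorm(length(mzv)) * (noise$baseline_rate > 0))
    piece[[nrow(panel) + 1L]] <- data.frame(scan = sc, mz = mzv,
                                            intensity = pmax(inten, 1))
  }

  if (noise$baseline_rate > 0) {
    n_noise <- stats::rpois(1L, noise$baseline_rate * n_scan)
    piece[[nrow(panel) + 2L]] <- data.frame(
      scan = sample.int(n_scan, n_noise, replace = TRUE),
      mz = stats::runif(n_noise, design$mz_window[1], design$mz_window[2]),
      intensity = stats::rexp(n_noise, rate = 1 / noise$baseline_mean)
    )
  }

  trace <- do.call(rbind, piece[!vapply(piece, is.null, logical(1))])
  trace <- trace[order(trace$scan, trace$mz), , drop = FALSE]
  trace <- data.frame(run_id = run_id, scan = trace$scan,
                      time_min = times[trace$scan], mz = trace$mz,
                      intensity = trace$intensity, stringsAsFactors = FALSE)
  rownames(trace) <- NULL

  truth_features <- data.frame(
    feature_id = panel$feature_id, name = panel$name,
    mz_true = panel$mz, mz_obs = mz_obs,
    mt_true = panel$mt, mt_obs = mt_obs,
    area = areas, amplitude = amp, sigma = panel$sigma,
    stringsAsFactors = FALSE
  )
  list(trace = trace,
       truth = list(features = truth_features, distortion = distortion,
                    group = group, run_id = run_id))
}

#' Simulate a full synthetic experiment
#'
#' Builds one shared 122-feature panel, then one run per sample of the
#' design, each with its own random migration-time distortion and m/z bias.
#'
#' @param design A [study_design()].
#' @param effects Planted effects (default [default_effects()]).
#' @param seed Master seed; the panel, per-run seeds and distortions are all
#'   derived from it.
#' @param noise A [noise_spec()].
#' @param noise_cv Abundance noise CV handed to each run's distortion.
#' @param refdb Reference database.
#' @param n_unknown Number of unknown features in the panel.
#' @return list with `runs` (list of [simulate_run()] results), `panel`,
#'   `samples`, `design`.
#' @export
simulate_experiment <- function(design = study_design(), effects = NULL,
                                seed, noise = noise_spec(), noise_cv = 0.2,
                                refdb = load_packaged_reference(),
                                n_unknown = 72L) {
  if (missing(seed)) stop("seed must be supplied", call. = FALSE)
  effects <- resolve_effects(effects, refdb)
  set.seed(seed)
  panel <- make_feature_panel(refdb, n_unknown = n_unknown,
                              mz_window = design$mz_window)
  n_run <- nrow(design$samples)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_run)
  distortions <- lapply(seq_len(n_run), function(i) {
    random_distortion(design$duration_min, noise_cv)
  })
  runs <- lapply(seq_len(n_run), function(i) {
    simulate_run(design, effects, distortions[[i]], seed = run_seeds[i],
                 panel = panel, refdb = refdb,
                 group = design$samples$group[i],
                 run_id = design$samples$sample[i], noise = noise)
  })
  list(runs = runs, panel = panel, samples = design$samples, design = design)
}

#' Simulate planted abundances without trace synthesis
#'
#' Draws the same per-sample feature areas the trace generator plants (group
#' effects plus log-normal noise) directly as a features-by-samples matrix.
#' Useful for studying the statistical stages at scale without paying for
#' scan-level synthesis; the trace-level pipeline is exercised by
#' [simulate_experiment()].
#'
#' @inheritParams simulate_experiment
#' @param noise_cv Abundance noise CV.
#' @return list with `areas` (features x samples matrix, rownames =
#'   feature ids), `panel`, `samples`.
#' @export
simulate_abundances <- function(design = study_design(), effects = NULL,
                                seed, noise_cv = 0.2,
                                refdb = load_packaged_reference(),
                                n_unknown = 72L) {
  if (missing(seed)) stop("seed must be supplied", call. = FALSE)
  effects <- resolve_effects(effects, refdb)
  set.seed(seed)
  panel <- make_feature_panel(refdb, n_unknown = n_unknown,
                              mz_window = design$mz_window)
  areas <- vapply(seq_len(nrow(design$samples)), function(i) {
    sample_areas(panel, design$samples$group[i], effects, noise_cv)
  }, numeric(nrow(panel)))
  dimnames(areas) <- list(panel$feature_id, design$samples$sample)
  list(areas = areas, panel = panel, samples = design$samples)
}

#' Write / read a raw trace as long-format CSV
#'
#' Interchange format: columns `run_id`, `time_min`, `mz`, `intensity`.
#'
#' @param trace Trace data.frame.
#' @param path Output path.
#' @return `read_trace` returns the trace data.frame (with a reconstructed
#'   `scan` index); `write_trace` returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace[c("run_id", "time_min", "mz", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "time_min", "mz", "intensity")
  if (!all(need %in% names(tr))) {
    stop("trace CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tr$scan <- match(tr$time_min, sort(unique(tr$time_min)))
  tr[order(tr$scan, tr$mz), ]
}
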