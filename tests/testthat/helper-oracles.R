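# Independent oracles and shared fixtures for the test suite.
# Oracles deliberately avoid the package's code paths.

# -- monoisotopic masses, hand-coded independently of mass_constants()
oracle_atomic <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069, Na = 22.98976928)
oracle_proton <- 1.00727646688
oracle_electron <- 0.00054857990

oracle_mass <- function(counts) sum(oracle_atomic[names(counts)] * counts)

# -- brute-force hypergeometric upper tail by enumerating all C(N, n) draws
bf_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)  # pathway = elements 1..K
}

# -- brute-force betweenness centrality by geodesic enumeration (BFS counts)
bf_betweenness <- function(members, edges) {
  n <- length(members)
  adj <- matrix(FALSE, n, n, dimnames = list(members, members))
  for (e in edges) adj[e[1], e[2]] <- adj[e[2], e[1]] <- TRUE
  dist_sigma <- function(s) {
    d <- rep(Inf, n); sig <- rep(0, n)
    d[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ])) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
        if (d[w] == d[v] + 1) sig[w] <- sig[w] + sig[v]
      }
      frontier <- unique(nxt)
    }
    list(d = d, sig = sig)
  }
  pre <- lapply(seq_len(n), dist_sigma)
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || is.infinite(pre[[s]]$d[t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (pre[[s]]$d[v] + pre[[v]]$d[t] == pre[[s]]$d[t]) {
        bc[v] <- bc[v] + pre[[s]]$sig[v] * pre[[v]]$sig[t] / pre[[s]]$sig[t]
      }
    }
  }
  stats::setNames(bc / 2, members)  # each unordered pair counted twice
}

# -- dense two-block PLS oracle via per-component SVD (no NIPALS iteration)
dense_pls2_svd <- function(X, y, ncomp) {
  y <- factor(y)
  Y <- stats::model.matrix(~ y - 1)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  Tm <- matrix(0, nrow(X), ncomp)
  for (h in seq_len(ncomp)) {
    w <- svd(crossprod(Xc, Yc))$u[, 1]
    tt <- drop(Xc %*% w)
    pl <- drop(crossprod(Xc, tt)) / sum(tt^2)
    ql <- drop(crossprod(Yc, tt)) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pl)
    Yc <- Yc - tcrossprod(tt, ql)
    Tm[, h] <- tt
  }
  Tm
}

# -- synthetic trace helpers ------------------------------------------------
# build a centroided trace from Gaussian peak specs (mz, mt, amplitude, sigma)
gauss_trace <- function(peaks, t_max = 10, dt = 0.01, run_id = "t1") {
  times <- seq(dt, t_max, by = dt)
  rows <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
    inten <- peaks$amplitude[i] *
      exp(-(times - peaks$mt[i])^2 / (2 * peaks$sigma[i]^2))
    keep <- inten >= 1
    data.frame(scan = which(keep), time_min = times[keep],
               mz = peaks$mz[i], intensity = inten[keep])
  }))
  rows <- rows[order(rows$scan, rows$mz), ]
  data.frame(run_id = run_id, rows[c("scan", "time_min", "mz", "intensity")])
}

# planted features that could merge during extraction (within the 5 mDa
# window and closer than one FWHM of the wider peak, with margin)
potential_merges <- function(truth_features) {
  tf <- truth_features
  cnt <- 0L
  n <- nrow(tf)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(tf$mz_obs[i] - tf$mz_obs[j]) <= 0.005 &&
        abs(tf$mt_obs[i] - tf$mt_obs[j]) <=
          2.355 * (tf$sigma[i] + tf$sigma[j])) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

planted_effect_names <- function() default_effects()$name

# -- memoised fixtures (built once per test run) ----------------------------
.fx <- new.env(parent = emptyenv())

fx_refdb <- function() {
  if (is.null(.fx$refdb)) .fx$refdb <- load_packaged_reference()
  .fx$refdb
}

# one default-noise run, extracted and calibrated
fx_run <- function() {
  if (is.null(.fx$run)) {
    refdb <- fx_refdb()
    set.seed(101)
    dist <- random_distortion()
    run <- simulate_run(study_design(), distortion = dist, seed = 202,
                        refdb = refdb, group = "Sym", run_id = "fx1")
    feats <- extract_features(run$trace,
                              exclude_mz = calibrant_series(7)$mz_theoretical)
    cal <- calibrate_run(run$trace, feats, refdb, duration_min = 50)
    .fx$run <- list(run = run, features = feats, cal = cal,
                    matches = match_features(cal$features, refdb))
  }
  .fx$run
}

# one noiseless identity-distortion run
fx_noiseless <- function() {
  if (is.null(.fx$noiseless)) {
    refdb <- fx_refdb()
    run <- simulate_run(study_design(),
                        distortion = run_distortion(noise_cv = 0),
                        seed = 303, refdb = refdb, group = "Ctrl",
                        run_id = "fx0", noise = noiseless())
    feats <- extract_features(run$trace,
                              exclude_mz = calibrant_series(7)$mz_theoretical)
    .fx$noiseless <- list(run = run, features = feats)
  }
  .fx$noiseless
}

# a full default experiment processed through identification (shared by the
# quantification and pipeline tests)
fx_experiment <- function() {
  if (is.null(.fx$expt)) {
    refdb <- fx_refdb()
    expt <- simulate_experiment(seed = 404, refdb = refdb)
    cal_mz <- calibrant_series(7)$mz_theoretical
    matches <- lapply(expt$runs, function(run) {
      feats <- extract_features(run$trace, exclude_mz = cal_mz)
      cal <- calibrate_run(run$trace, feats, refdb, duration_min = 50)
      match_features(cal$features, refdb)
    })
    names(matches) <- expt$samples$sample
    .fx$expt <- list(expt = expt, matches = matches)
  }
  .fx$expt
}

# scaled matrix + labels from planted abundances (matrix-level route)
fx_scaled_abundances <- function(seed = 12, effects = NULL, noise_cv = 0.2) {
  sim <- simulate_abundances(effects = effects, seed = seed,
                             noise_cv = noise_cv)
  mat <- abundance_matrix(sim$areas, sim$samples)
  list(X = t(preprocess(mat)$values),
       Xlog = t(preprocess(mat, stop_at = "log10")$values),
       y = sim$samples$group, sim = sim)
}
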