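test_that("EIC construction centers on planted species", {
  peaks <- data.frame(mz = c(147.1128, 300.2), mt = c(5, 8),
                      amplitude = 1e5, sigma = 0.1)
  tr <- gauss_trace(peaks)
  eics <- build_eics(tr)
  expect_length(eics, 2L)
  expect_lt(abs(eics[[1]]$target_mz - 147.1128), 0.005)
  # each EIC covers the full scan grid; scans with no centroid in the
  # window contribute zero
  expect_identical(length(eics[[1]]$intensity), length(eics[[1]]$time))
  expect_true(any(eics[[1]]$intensity == 0))
})

test_that("species below the m/z resolution merge into one candidate", {
  peaks <- data.frame(mz = c(200.000, 200.004), mt = c(3, 7),
                      amplitude = 1e5, sigma = 0.1)
  eics <- build_eics(gauss_trace(peaks))
  expect_length(eics, 1L)  # 4 mDa gap < 5 mDa linkage
  # but 8 mDa apart resolves into two candidates
  peaks2 <- data.frame(mz = c(200.000, 200.008), mt = c(3, 7),
                       amplitude = 1e5, sigma = 0.1)
  expect_length(build_eics(gauss_trace(peaks2)), 2L)
})

test_that("degenerate traces are rejected", {
  expect_error(build_eics(data.frame()), "empty trace")
  tr <- gauss_trace(data.frame(mz = 100, mt = 5, amplitude = 1e4,
                               sigma = 0.1))
  shuffled <- tr[rev(seq_len(nrow(tr))), ]
  expect_error(build_eics(shuffled), "non-decreasing")
  expect_error(extract_features(shuffled), "non-decreasing")
})

test_that("trapezoidal area matches the analytic Gaussian integral", {
  A <- 2e4; sigma <- 0.08
  tt <- seq(0.005, 10, by = 0.005)
  eic <- structure(list(target_mz = 150, tol_mda = 5, time = tt,
                        intensity = A * exp(-(tt - 5)^2 / (2 * sigma^2)),
                        mz = rep(150, length(tt))), class = "eic")
  pk <- detect_peaks(eic, min_noise = 1)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$area - A * sigma * sqrt(2 * pi)) /
              (A * sigma * sqrt(2 * pi)), 0.01)
  expect_equal(pk$mt_min, 5, tolerance = 0.005)
})

test_that("pure noise yields no features and short EICs error", {
  set.seed(3)
  tt <- seq(0.01, 10, by = 0.01)
  eic <- structure(list(target_mz = 150, tol_mda = 5, time = tt,
                        intensity = abs(rnorm(length(tt), 0, 10)),
                        mz = rep(150, length(tt))), class = "eic")
  expect_identical(nrow(detect_peaks(eic)), 0L)
  short <- structure(list(target_mz = 1, tol_mda = 5, time = 1:4,
                          intensity = c(0, 5, 0, 0), mz = rep(1, 4)),
                     class = "eic")
  expect_error(detect_peaks(short), "at least 5")
})

test_that("areas are linear in intensity and invariant in m/z and MT", {
  fx <- fx_noiseless()
  tr2 <- fx$run$trace
  tr2$intensity <- tr2$intensity * 2
  f1 <- fx$features
  f2 <- extract_features(tr2, exclude_mz = calibrant_series(7)$mz_theoretical)
  expect_identical(nrow(f1), nrow(f2))
  ord1 <- order(f1$mz, f1$mt_min); ord2 <- order(f2$mz, f2$mt_min)
  expect_equal(f2$mz[ord2], f1$mz[ord1], tolerance = 1e-9)
  expect_equal(f2$mt_min[ord2], f1$mt_min[ord1], tolerance = 1e-9)
  expect_equal(f2$area[ord2], f1$area[ord1] * 2, tolerance = 1e-6)
})

test_that("raising the S/N gate never increases the feature count", {
  fx <- fx_run()
  counts <- vapply(c(5, 15, 30, 60, 120), function(s) {
    nrow(extract_features(fx$run$trace, sn_min = s,
                          exclude_mz = calibrant_series(7)$mz_theoretical))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("apex picking agrees with a brute-force scan on short EICs", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 50
    tt <- seq_len(n) / 10
    x <- abs(rnorm(n, 0, 1))
    # add 1-3 clear triangular peaks
    for (k in seq_len(sample(1:3, 1))) {
      ctr <- sample(5:(n - 5), 1)
      x[(ctr - 3):(ctr + 3)] <- x[(ctr - 3):(ctr + 3)] +
        runif(1, 50, 200) * c(0.1, 0.3, 0.7, 1, 0.7, 0.3, 0.1)
    }
    eic <- structure(list(target_mz = 100, tol_mda = 5, time = tt,
                          intensity = x, mz = rep(100, n)), class = "eic")
    pk <- detect_peaks(eic, sn_min = 15)
    # brute force: strict rise on the left, fall-or-equal on the right,
    # above gate, with >= 3 consecutive half-height points
    noise <- local({
      low <- sort(x)[1:25]
      max(1.4826 * median(abs(low - median(low))), 1)
    })
    bf <- integer(0)
    for (i in 2:(n - 1)) {
      if (x[i] > x[i - 1] && x[i] >= x[i + 1] && x[i] > 15 * noise) {
        l <- i; while (l > 1 && x[l - 1] >= x[i] / 2) l <- l - 1
        r <- i; while (r < n && x[r + 1] >= x[i] / 2) r <- r + 1
        if (r - l + 1 >= 3) bf <- c(bf, i)
      }
    }
    expect_equal(sort(pk$mt_min), sort(tt[bf]))
  }
})

test_that("noiseless run recovers the planted feature panel", {
  fx <- fx_noiseless()
  n_merge <- potential_merges(fx$run$truth$features)
  expect_gte(nrow(fx$features), 122L - n_merge)
  expect_lte(nrow(fx$features), 122L)
  if (n_merge == 0L) expect_identical(nrow(fx$features), 122L)
})

test_that("default-noise run recovers planted features above the gate", {
  fx <- fx_run()
  tf <- fx$run$truth$features
  feats <- fx$features
  hit <- vapply(seq_len(nrow(tf)), function(i) {
    any(abs(feats$mz - tf$mz_obs[i]) <= 0.005 &
          abs(feats$mt_min - tf$mt_obs[i]) <= 0.2)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  expect_true(all(feats$sn > 15))  # nothing below the gate is reported
})
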