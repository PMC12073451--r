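test_that("matrix assembly reconstructs the planted panel across runs", {
  fe <- fx_experiment()
  mat <- build_matrix(fe$matches, fe$expt$samples)
  expect_identical(ncol(mat$values), 11L)
  expect_identical(mat$samples$group, fe$expt$samples$group)
  # unknown features cluster back to the 72 planted unknowns
  expect_identical(sum(mat$features$kind == "unknown"), 72L)
  # identified rows are the union of per-run identified names
  nm <- sort(unique(unlist(lapply(fe$matches, function(m) {
    m$ref_name[m$ref_name != "unknown"]
  }))))
  expect_identical(sort(mat$features$feature_id[
    mat$features$kind == "identified"]), nm)
  expect_identical(nrow(mat$values),
                   length(nm) + 72L)
  expect_true(all(mat$values > 0))
})

test_that("missing observations are imputed at half the feature minimum", {
  fe <- fx_experiment()
  drop_run <- fe$matches
  victim <- "Lysine"
  m1 <- drop_run[[1]]
  drop_run[[1]] <- m1[!(m1$ref_name %in% victim), ]
  mat <- build_matrix(drop_run, fe$expt$samples)
  full <- build_matrix(fe$matches, fe$expt$samples)
  row <- mat$values[victim, ]
  expect_equal(unname(row[1]), min(row[-1]) / 2)
  # observed cells are never altered by imputation
  expect_equal(row[-1], full$values[victim, -1])
  expect_identical(mat$n_imputed, full$n_imputed + 1L)
})

test_that("matrix assembly needs at least two runs", {
  fe <- fx_experiment()
  expect_error(build_matrix(fe$matches[1], fe$expt$samples), "at least 2")
})

test_that("replicate QC gates flag high-variance features", {
  # tight abundances pass both gates
  sim <- simulate_abundances(seed = 41, noise_cv = 0.01)
  mat <- abundance_matrix(sim$areas, sim$samples)
  mat$mt_values[] <- rep(sim$panel$mt, ncol(mat$values))  # exact MTs
  qc <- qc_filter(mat)
  expect_identical(length(qc$matrix$qc_failed), 0L)
  expect_true(all(qc$report$mt_pass & qc$report$area_pass))

  # planted 40% abundance CV mostly fails the 25% area gate
  sim40 <- simulate_abundances(seed = 42, noise_cv = 0.4)
  mat40 <- abundance_matrix(sim40$areas, sim40$samples)
  mat40$mt_values[] <- rep(sim40$panel$mt, ncol(mat40$values))
  qc40 <- qc_filter(mat40)
  expect_gt(length(qc40$matrix$qc_failed), nrow(mat40$values) / 2)
  # constant feature: RSD 0, passes
  matc <- abundance_matrix(matrix(1000, 3, 11,
                                  dimnames = list(paste0("f", 1:3), NULL)),
                           sim40$samples)
  matc$mt_values[] <- 20
  expect_identical(length(qc_filter(matc)$matrix$qc_failed), 0L)
  # drop = TRUE removes the failures
  dropped <- qc_filter(mat40, drop = TRUE)
  expect_identical(nrow(dropped$matrix$values),
                   nrow(mat40$values) - length(dropped$matrix$qc_failed))
})

test_that("preprocessing normalizes, transforms, and scales in order", {
  sim <- simulate_abundances(seed = 43)
  mat <- abundance_matrix(sim$areas, sim$samples)
  sc <- preprocess(mat)
  expect_identical(sc$state, "scaled")
  # autoscaled rows: mean 0, sd 1
  expect_lt(max(abs(rowMeans(sc$values))), 1e-10)
  expect_equal(unname(apply(sc$values, 1, sd)),
               rep(1, nrow(sc$values)), tolerance = 1e-9)
  # after median normalization all sample medians are equal
  lg <- preprocess(mat, stop_at = "log10")
  med <- apply(10^lg$values, 2, median)
  expect_lt(diff(range(med)) / med[1], 1e-12)
  # per-sample multiplicative scaling is removed by the normalization
  # (scale a sample whose median is not the reference median, so the
  # median-of-medians reference itself is unchanged)
  j <- which.max(apply(mat$values, 2, median))
  mat2 <- mat
  mat2$values[, j] <- mat2$values[, j] * 2
  lg2 <- preprocess(mat2, stop_at = "log10")
  expect_equal(lg2$values[, j], lg$values[, j], tolerance = 1e-12)
})

test_that("degenerate matrices are handled deterministically", {
  samples <- data.frame(sample = paste0("s", 1:4),
                        group = c("A", "A", "B", "B"))
  const <- abundance_matrix(matrix(100, 5, 4), samples)
  sc <- preprocess(const)
  expect_true(all(sc$values == 0))  # sd-0 rows map to zero vectors
  zero <- abundance_matrix(matrix(0, 5, 4), samples)
  expect_error(preprocess(zero), "median")
  expect_error(preprocess(preprocess(const)), "raw")
})
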