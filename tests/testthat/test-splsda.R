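test_that("dense fit agrees with the SVD-based PLS oracle", {
  d <- fx_scaled_abundances(seed = 12)
  fit <- fit_splsda(d$X, d$y, ncomp = 2, keepX = ncol(d$X))
  oracle <- dense_pls2_svd(d$X, d$y, 2)
  for (h in 1:2) {
    s <- sign(sum(fit$scores[, h] * oracle[, h]))
    expect_lt(max(abs(fit$scores[, h] - s * oracle[, h])), 1e-6)
  }
})

test_that("model structure satisfies its invariants", {
  d <- fx_scaled_abundances(seed = 12)
  fit <- fit_splsda(d$X, d$y, ncomp = 3, keepX = 30)
  # unit-norm weights, keepX sparsity, orthogonal scores
  expect_equal(unname(colSums(fit$weights^2)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(colSums(fit$weights != 0) <= 30))
  gram <- crossprod(fit$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # deflation removes variance monotonically
  expect_true(all(fit$explained_variance > 0))
  expect_lte(sum(fit$explained_variance), 1 + 1e-9)
})

test_that("a single discriminative feature is found at keepX = 1", {
  set.seed(9)
  n <- 12
  X <- matrix(rnorm(n * 20, sd = 0.1), n, 20)
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", 7] <- X[y == "b", 7] + 5
  X <- scale(X)
  fit <- fit_splsda(X, y, ncomp = 1, keepX = 1)
  expect_identical(unname(which(fit$weights[, 1] != 0)), 7L)
  expect_equal(unname(abs(fit$weights[7, 1])), 1, tolerance = 1e-12)
})

test_that("degenerate fits are rejected", {
  d <- fx_scaled_abundances(seed = 12)
  expect_error(fit_splsda(d$X, d$y, ncomp = 0), ">= 1")
  expect_error(fit_splsda(d$X, d$y, ncomp = 2, keepX = ncol(d$X) + 1),
               "keepX")
  expect_error(fit_splsda(d$X, rep("Sym", nrow(d$X)), ncomp = 1),
               "two classes")
  expect_error(cross_validate(d$X, d$y, folds = 1), ">= 2")
})

test_that("cross-validation separates strongly separable groups", {
  eff <- default_effects()
  eff$Sym <- eff$Sym * 4  # 2.0 log10 units
  eff$Axe <- eff$Axe * 4
  d <- fx_scaled_abundances(seed = 11, effects = eff, noise_cv = 0.05)
  cv <- cross_validate(d$X, d$y, max_comp = 2, folds = 10, seed = 5)
  # far below the 2/3 chance level (the three-feature Axe contrast keeps a
  # residual error at this sample size; see the methods vignette)
  expect_lte(min(cv$ber), 0.2)
  expect_true(all(cv$ber >= 0 & cv$ber <= 1))
  expect_identical(sort(unique(cv$fold_assignment)), 1:10)
})

test_that("stratified folds keep all classes in every training split", {
  d <- fx_scaled_abundances(seed = 12)
  cv <- cross_validate(d$X, d$y, max_comp = 1, folds = 10, seed = 2)
  for (f in unique(cv$fold_assignment)) {
    expect_identical(length(unique(d$y[cv$fold_assignment != f])), 3L)
  }
})

test_that("feature ranking reports planted associations", {
  d <- fx_scaled_abundances(seed = 12)
  fit <- fit_splsda(d$X, d$y, ncomp = 2, keepX = 30)
  rk <- rank_features(fit, top_n = 30)
  expect_lte(nrow(rk), 30L)
  expect_true(all(diff(rk$influence) <= 1e-12))
  # Sym-enriched planted metabolites present in the ranking carry Sym
  sym9 <- paste0("ref_", default_effects()$name[1:9])
  present <- rk[rk$feature %in% sym9, ]
  expect_gt(nrow(present), 0L)
  expect_true(all(present$group == "Sym"))
  # requesting more than the non-zero count notes the shortfall
  fit1 <- fit_splsda(d$X, d$y, ncomp = 1, keepX = 5)
  rk1 <- rank_features(fit1, top_n = 30)
  expect_identical(nrow(rk1), 5L)
  expect_identical(attr(rk1, "shortfall"), 25L)
})

test_that("VIP ranking is available and non-negative", {
  d <- fx_scaled_abundances(seed = 12)
  fit <- fit_splsda(d$X, d$y, ncomp = 2, keepX = 30)
  vip <- splsda_vip(fit)
  expect_true(all(vip >= 0))
  rk <- rank_features(fit, top_n = 10, ranking = "vip")
  expect_identical(nrow(rk), 10L)
})
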