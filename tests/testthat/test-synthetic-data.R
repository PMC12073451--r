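test_that("calibrant series matches the hand-computed cluster masses", {
  s <- calibrant_series(3)
  # frozen from the independent atomic-mass sum: Na+ + n * NaHCO2
  expect_equal(round(s$mz_theoretical[1], 4), 90.9766)
  expect_equal(round(s$mz_theoretical[2], 4), 158.9641)
  expect_equal(s$mz_theoretical[1],
               (oracle_atomic[["Na"]] - oracle_electron) +
                 (oracle_atomic[["Na"]] + oracle_atomic[["H"]] +
                    oracle_atomic[["C"]] + 2 * oracle_atomic[["O"]]))
  expect_error(calibrant_series(2), "at least 3")
})

test_that("simulated calibrants carry the planted ppm bias", {
  s <- simulate_calibrant_series(6, ppm_bias = 5)
  expect_lt(max(abs(s$mz / s$mz_theoretical - 1 - 5e-6)), 1e-12)
})

test_that("run simulation is reproducible and respects invariants", {
  refdb <- fx_refdb()
  d <- study_design()
  dist <- run_distortion(c0 = 0.2, c1 = 1.01, c2 = 1e-4, c3 = -5e-7,
                         ppm_bias = 4)
  r1 <- simulate_run(d, distortion = dist, seed = 5, refdb = refdb)
  r2 <- simulate_run(d, distortion = dist, seed = 5, refdb = refdb)
  expect_identical(r1$trace, r2$trace)

  tf <- r1$truth$features
  expect_identical(nrow(tf), 122L)
  expect_identical(sum(!is.na(tf$name)), 50L)
  expect_identical(sum(is.na(tf$name)), 72L)
  expect_true(all(r1$trace$intensity >= 0))
  expect_true(all(tf$mz_true >= 50 & tf$mz_true <= 500))
  expect_false(is.unsorted(r1$trace$time_min))

  # unknown features respect the exclusion zone around reference m/z
  unk_mz <- tf$mz_true[is.na(tf$name)]
  min_gap <- vapply(unk_mz, function(m) {
    min(abs(m - refdb$mz_theoretical))
  }, numeric(1))
  expect_true(all(min_gap > 0.01))
})

test_that("ground-truth areas are independent of the MT distortion", {
  refdb <- fx_refdb()
  d <- study_design()
  set.seed(1); panel <- make_feature_panel(refdb)
  a <- simulate_run(d, distortion = run_distortion(), seed = 9,
                    panel = panel, refdb = refdb)
  b <- simulate_run(d, distortion = run_distortion(c0 = 0.4, c1 = 1.04,
                                                   c2 = 1e-4, c3 = 1e-6),
                    seed = 9, panel = panel, refdb = refdb)
  expect_equal(a$truth$features$area, b$truth$features$area)
  expect_false(isTRUE(all.equal(a$truth$features$mt_obs,
                                b$truth$features$mt_obs)))
})

test_that("noiseless identity run puts apexes at reference times", {
  fx <- fx_noiseless()
  m <- match_features(apply_calibration(fx$features, calibration_model()),
                      fx_refdb())
  iden <- m[m$ref_name != "unknown", ]
  ref_mt <- fx_refdb()$ref_mt_min[match(iden$ref_name, fx_refdb()$name)]
  # apex within one scan interval of the planted reference time
  expect_true(all(abs(iden$mt_min - ref_mt) <= 0.02 + 1e-9))
})

test_that("planted group effects are recovered from replicate abundances", {
  sim <- simulate_abundances(seed = 31)
  lv <- log10(sim$areas)
  sym_cols <- sim$samples$group == "Sym"
  ctrl_cols <- sim$samples$group == "Ctrl"
  for (nm in c("Lysine", "Pyridoxine")) {
    row <- lv[paste0("ref_", nm), ]
    diffs <- mean(row[sym_cols]) - mean(row[ctrl_cols])
    se <- sqrt(stats::var(row[sym_cols]) / sum(sym_cols) +
                 stats::var(row[ctrl_cols]) / sum(ctrl_cols))
    expect_lt(abs(diffs - 0.5), 3 * se)
  }
  # a feature with no planted effect stays flat
  row0 <- lv["ref_Valine", ]
  d0 <- mean(row0[sym_cols]) - mean(row0[ctrl_cols])
  se0 <- sqrt(stats::var(row0[sym_cols]) / 4 + stats::var(row0[ctrl_cols]) / 4)
  expect_lt(abs(d0), 3 * se0 + 1e-12)
})

test_that("configuration errors are caught", {
  expect_error(run_distortion(c1 = -1), "monotone")
  expect_error(run_distortion(ppm_bias = 30), "ppm_bias")
  expect_error(simulate_run(study_design(), distortion = run_distortion()),
               "seed")
  bad_eff <- data.frame(name = "NotAMetabolite", Ctrl = 0, Sym = 1, Axe = 0)
  expect_error(simulate_experiment(effects = bad_eff, seed = 1),
               "not in reference database")
  expect_error(study_design(n_axe = 1L))
})
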