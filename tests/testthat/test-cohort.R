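test_that("cohort generation is deterministic in the config seed", {
  a <- make_cohort(quick_cfg(n_patients = 3, n_channels = 2, seed = 5))
  b <- make_cohort(quick_cfg(n_patients = 3, n_channels = 2, seed = 5))
  c <- make_cohort(quick_cfg(n_patients = 3, n_channels = 2, seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$patients[[1]]$spectra_pre$power,
                         c$patients[[1]]$spectra_pre$power))
  # generation does not disturb the caller's RNG stream
  set.seed(1); x <- rnorm(1)
  set.seed(1); invisible(make_cohort(quick_cfg(n_patients = 2,
                                               n_channels = 1)))
  expect_identical(rnorm(1), x)
})

test_that("stored ground truth is internally consistent", {
  co <- make_cohort(quick_cfg(n_patients = 6, n_channels = 3, seed = 9))
  gt <- ground_truth_features(co)
  cl <- co$clinical[match(gt$patient, co$clinical$patient), ]
  # electrode-averaged true exponents track the patient-level draws
  expect_lt(max(abs(gt$exponent_pre - cl$exponent_pre_true)), 0.1)
  expect_lt(max(abs(-gt$exponent_diff - cl$exponent_shift_true)), 0.15)
  # channel offsets: the post offset absorbs the pivot rotation
  resid <- vapply(seq_along(co$patients), function(i) {
    p <- co$patients[[i]]
    sh <- cl$exponent_shift_true[cl$patient == p$id]
    d_off <- mean(vapply(p$truth_post, `[[`, numeric(1), "offset")) -
      mean(vapply(p$truth_pre, `[[`, numeric(1), "offset"))
    d_off - sh * log10(co$config$pivot_hz)
  }, numeric(1))
  expect_lt(abs(mean(resid)), 0.05)
})

test_that("a pure exponent rotation raises band power but not true oscillation power", {
  bp <- lapply(band_peak_defaults("ECT"), function(b) {
    b$emergence_post <- b$emergence_pre
    b$height_post <- b$height_pre
    b
  })
  cfg <- cohort_config("ECT", n_patients = 40, n_channels = 8,
                       band_peaks = bp, seed = 14)
  co <- make_cohort(cfg)
  gt <- ground_truth_features(co)
  # generated spectra: delta band power rises after the rotation
  dpd <- vapply(co$patients, function(p) {
    band_power(p$spectra_pre, "delta") - band_power(p$spectra_post, "delta")
  }, numeric(1))
  expect_lt(mean(dpd), 0)  # pre minus post negative: post is higher
  # true oscillation parameters are exchangeable pre/post
  osc <- gt$alpha_osc_diff[!is.na(gt$alpha_osc_diff)]
  expect_lt(abs(mean(osc)), 0.1)
  expect_equal(mean(gt$alpha_abundance_diff), 0, tolerance = 0.15)
})

test_that("fitted cohort features recover the planted treatment effect", {
  co <- make_cohort(quick_cfg(seed = 2))
  fits <- fit_cohort(co)
  feats <- cohort_features(co, fits)
  expect_true(all(c("patient", "treatment", "hamd_pre", "hamd_post",
                    "exponent_pre", "exponent_post", "exponent_diff",
                    "delta_power_diff", "delta_abundance_pre",
                    "n_electrodes_retained") %in% names(feats)))
  expect_lte(nrow(feats), co$config$n_patients)
  expect_gte(nrow(feats), co$config$n_patients - 2L)
  cl <- co$clinical[match(feats$patient, co$clinical$patient), ]
  expect_lt(max(abs(feats$exponent_pre - cl$exponent_pre_true)), 0.15)
  # planted slowing: the exponent rises after treatment
  expect_lt(mean(feats$exponent_diff), -0.1)
  # the battery covers all eight features with Holm metadata
  bat <- eeg_feature_tests(feats)
  expect_identical(nrow(bat$tests), 8L)
  expect_setequal(bat$tests$feature,
                  c("exponent", "delta_band_power",
                    "delta_oscillation_power", "delta_abundance",
                    "theta_oscillation_power", "theta_abundance",
                    "alpha_oscillation_power", "alpha_abundance"))
  valid <- !is.na(bat$tests$p)
  expect_setequal(sort(bat$tests$holm_rank[valid]), seq_len(sum(valid)))
})

test_that("the pipeline produces a complete, byte-reproducible report", {
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  cfg <- run_config(quick_cfg(n_patients = 6, seed = 3), out_dir = out1)
  rep1 <- suppressMessages(run_pipeline(cfg))
  expect_s3_class(rep1, "run_report")
  expect_identical(nrow(rep1$eeg_tests), 8L)
  expect_named(rep1$band_regressions, c("delta", "theta", "alpha"))
  expect_true(rep1$clinical$remission_rate >= 0 &&
                rep1$clinical$remission_rate <= 100)
  expect_identical(rep1$clinical$hamd_test$test_name, "wilcoxon")
  for (f in c("features.csv", "fits.csv", "eeg_tests.csv", "report.json")) {
    expect_true(file.exists(file.path(out1, f)))
  }
  js <- jsonlite::read_json(file.path(out1, "report.json"))
  expect_identical(js$seed, 3L)
  expect_length(js$eeg_tests, 8L)
  cfg2 <- run_config(quick_cfg(n_patients = 6, seed = 3), out_dir = out2)
  suppressMessages(run_pipeline(cfg2))
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("null cohorts rarely produce a Holm-corrected exponent rejection", {
  rejs <- vapply(1:20, function(s) {
    co <- make_cohort(null_cfg(seed = 1000 + s))
    feats <- suppressMessages(cohort_features(co, fit_cohort(co)))
    bat <- suppressWarnings(eeg_feature_tests(feats))
    isTRUE(bat$tests$reject_stepdown[bat$tests$feature == "exponent"])
  }, logical(1))
  expect_lte(mean(rejs), 0.15)
})
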