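test_that("band power follows its defining identities and the slowing ambiguity", {
  flat <- make_spectrum(spectrum_spec(offset = -12, exponent = 0))
  for (b in band_definitions()$name) {
    expect_equal(band_power(flat, b), -12)
  }
  # steepening about a 30 Hz pivot raises delta band power with no true
  # delta oscillation change
  base <- spectrum_spec(offset = -11.6, exponent = 0.9)
  rot <- spectrum_spec(offset = -11.6 + 0.4 * log10(30), exponent = 1.3)
  expect_gt(band_power(make_spectrum(rot), "delta"),
            band_power(make_spectrum(base), "delta"))
  # a true delta oscillation raises band power at a fixed exponent
  osc <- spectrum_spec(offset = -11.6, exponent = 0.9,
                       peaks = data.frame(center = 2.5, height = 0.5, sd = 1))
  expect_gt(band_power(make_spectrum(osc), "delta"),
            band_power(make_spectrum(base), "delta"))
  expect_error(band_power(make_spectrum(base), data.frame(name = "x", lo = 40,
                                                          hi = 50)), "band")
})

test_that("band peak selection takes the in-band argmax with fixed boundaries", {
  sp <- spectrum_spec(offset = -11.5, exponent = 1,
                      peaks = data.frame(center = c(4.8, 6.2),
                                         height = c(0.3, 0.6),
                                         sd = c(0.7, 0.9)))
  fit <- fit_of_spec(sp)
  pk <- select_band_peak(fit, "theta")
  expect_equal(pk$center, 6.2, tolerance = 0.2)
  expect_null(select_band_peak(fit, "delta"))
  # boundary convention: a peak at exactly 4 Hz belongs to theta
  fit4 <- fit
  fit4$peaks <- data.frame(center = 4, height = 0.5, sd = 1, bandwidth = 2)
  expect_null(select_band_peak(fit4, "delta"))
  expect_equal(select_band_peak(fit4, "theta")$center, 4)
  # alpha closes at 12 Hz
  fit12 <- fit
  fit12$peaks <- data.frame(center = 12, height = 0.5, sd = 1, bandwidth = 2)
  expect_equal(select_band_peak(fit12, "alpha")$center, 12)
})

test_that("the paired quality filter removes electrodes and patients symmetrically", {
  pre <- list(A = stub_fit(0.95), B = stub_fit(0.99), C = stub_fit(1))
  post <- list(A = stub_fit(0.70), B = stub_fit(0.92), C = stub_fit(1))
  expect_setequal(quality_filter(pre, post), c("B", "C"))
  all1 <- list(A = stub_fit(1), B = stub_fit(1))
  expect_setequal(quality_filter(all1, all1), c("A", "B"))
  expect_length(quality_filter(list(A = stub_fit(0.5)),
                               list(A = stub_fit(0.9))), 0)
  expect_error(quality_filter(pre, post[1:2]), "labels")
})

test_that("abundance is the fraction of retained electrodes with a band peak", {
  with_pk <- fit_of_spec(spectrum_spec(offset = -11.5, exponent = 1,
                                       peaks = data.frame(center = 6,
                                                          height = 0.5,
                                                          sd = 1)))
  without <- fit_of_spec(spectrum_spec(offset = -11.5, exponent = 1))
  fits <- list(A = with_pk, B = with_pk, C = without, D = without)
  expect_equal(abundance(fits, "theta"), 0.5)
  expect_equal(abundance(fits, "theta", retained = c("A", "B")), 1)
  expect_equal(abundance(fits, "delta"), 0)
  expect_error(abundance(fits, "theta", retained = character()), "retained")
  # invariance to electrode order and power rescaling
  expect_equal(abundance(rev(fits), "theta"), 0.5)
})

test_that("per-electrode emergence probability is recovered as mean abundance", {
  cfg <- cohort_config("ECT", n_patients = 50, n_channels = 20, seed = 21,
                       band_peaks = list(
                         delta = list(emergence_pre = 0.4, emergence_post = 0.4,
                                      height_pre = 0.4, height_post = 0.4,
                                      height_sd = 0.05, center = 2.5,
                                      center_jitter = 0.3,
                                      sd_range = c(0.6, 1.2)),
                         theta = list(emergence_pre = 0, emergence_post = 0,
                                      height_pre = 0.3, height_post = 0.3,
                                      height_sd = 0.05, center = 5.5,
                                      center_jitter = 0.3,
                                      sd_range = c(0.6, 1.2)),
                         alpha = list(emergence_pre = 0, emergence_post = 0,
                                      height_pre = 1, height_post = 1,
                                      height_sd = 0.1, center = 10,
                                      center_jitter = 0.5,
                                      sd_range = c(0.8, 1.5))))
  gt <- ground_truth_features(make_cohort(cfg))
  expect_equal(mean(gt$delta_abundance_pre), 0.4, tolerance = 0.1)
})

test_that("patient features average electrodes and keep the pre-minus-post sign", {
  sp_pre <- spectrum_spec(offset = -11.6, exponent = 0.9)
  sp_post <- spectrum_spec(offset = -11.6 + 0.4 * log10(20), exponent = 1.3)
  mk <- function(sp, n) {
    fits <- lapply(seq_len(n), function(i) fit_of_spec(sp))
    names(fits) <- paste0("E", seq_len(n))
    fits
  }
  ps_pre <- make_spectrum(sp_pre, n_channels = 3)
  ps_post <- make_spectrum(sp_post, n_channels = 3)
  names_fix <- function(ps) { ps$channels <- paste0("E", 1:3); rownames(ps$power) <- ps$channels; ps }
  ps_pre <- names_fix(ps_pre); ps_post <- names_fix(ps_post)
  row <- patient_features(mk(sp_pre, 3), mk(sp_post, 3), ps_pre, ps_post)
  # identical electrodes: average equals the per-electrode value
  expect_equal(row$exponent_pre, 0.9, tolerance = 1e-3)
  # a post-treatment exponent increase gives a negative pre-minus-post diff
  expect_lt(row$exponent_diff, 0)
  expect_equal(row$exponent_diff, row$exponent_pre - row$exponent_post)
  expect_identical(row$n_electrodes_retained, 3L)
})

test_that("oscillation power never imputes zeros for peakless electrodes", {
  sp_pk <- spectrum_spec(offset = -11.5, exponent = 1,
                         peaks = data.frame(center = 6, height = 0.5, sd = 1))
  sp_no <- spectrum_spec(offset = -11.5, exponent = 1)
  f_pk <- fit_of_spec(sp_pk)
  f_no <- fit_of_spec(sp_no)
  ps2 <- make_spectrum(sp_pk, n_channels = 2)
  ps2$channels <- c("A", "B"); rownames(ps2$power) <- ps2$channels
  ps3 <- make_spectrum(sp_pk, n_channels = 3)
  ps3$channels <- c("A", "B", "C"); rownames(ps3$power) <- ps3$channels
  two <- patient_features(list(A = f_pk, B = f_pk),
                          list(A = f_pk, B = f_pk), ps2, ps2)
  three <- patient_features(list(A = f_pk, B = f_pk, C = f_no),
                            list(A = f_pk, B = f_pk, C = f_no), ps3, ps3)
  expect_equal(three$theta_osc_pre, two$theta_osc_pre)
  expect_lt(three$theta_abundance_pre, two$theta_abundance_pre)
})

test_that("oscillation emergence is captured as absent-then-present with rising abundance", {
  sp_pk <- spectrum_spec(offset = -11.5, exponent = 1,
                         peaks = data.frame(center = 6, height = 0.5, sd = 1))
  sp_no <- spectrum_spec(offset = -11.5, exponent = 1)
  f_pk <- fit_of_spec(sp_pk)
  f_no <- fit_of_spec(sp_no)
  labs <- c("A", "B", "C", "D")
  ps <- make_spectrum(sp_no, n_channels = 4)
  ps$channels <- labs; rownames(ps$power) <- labs
  pre <- list(A = f_no, B = f_no, C = f_no, D = f_no)
  post <- list(A = f_pk, B = f_pk, C = f_no, D = f_no)
  row <- patient_features(pre, post, ps, ps)
  expect_true(is.na(row$theta_osc_pre))
  expect_false(is.na(row$theta_osc_post))
  expect_equal(row$theta_abundance_pre, 0)
  expect_equal(row$theta_abundance_post, 0.5)
  # such a patient is excluded from the paired oscillation-power comparison
  expect_true(is.na(row$theta_osc_diff))
})
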