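# small cohort configuration used across tests (fast to fit)
quick_cfg <- function(..., n_patients = 8, n_channels = 4, seed = 1) {
  cohort_config("ECT", n_patients = n_patients, n_channels = n_channels,
                seed = seed, ...)
}

# configuration with no pre/post differences at all (null condition)
null_cfg <- function(seed, n_patients = 10, n_channels = 2) {
  bp <- list(
    delta = list(emergence_pre = 0.2, emergence_post = 0.2,
                 height_pre = 0.3, height_post = 0.3, height_sd = 0.08,
                 center = 2.5, center_jitter = 0.5, sd_range = c(0.6, 1.5)),
    theta = list(emergence_pre = 0.4, emergence_post = 0.4,
                 height_pre = 0.4, height_post = 0.4, height_sd = 0.1,
                 center = 5.5, center_jitter = 0.6, sd_range = c(0.6, 1.5)),
    alpha = list(emergence_pre = 0.9, emergence_post = 0.9,
                 height_pre = 1.1, height_post = 1.1, height_sd = 0.3,
                 center = 10, center_jitter = 1, sd_range = c(0.8, 2)))
  cohort_config("ECT", n_patients = n_patients, n_channels = n_channels,
                exponent_shift_mean = 0, exponent_shift_sd = 0.15,
                band_peaks = bp, hamd_treatment_effect = 0,
                hamd_effect_on_baseline_exponent = 0, seed = seed)
}

# brute-force Cliff's delta over all cross pairs
cliffs_brute <- function(x, y) {
  s <- 0
  for (xi in x) for (yi in y) s <- s + sign(xi - yi)
  s / (length(x) * length(y))
}

# exact two-sided signed-rank p by enumeration over all 2^n sign vectors
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- 2^n
  count <- 0
  for (mask in 0:(total - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    tp <- sum(r[signs])
    if (min(tp, sum(r) - tp) <= w_obs) count <- count + 1
  }
  min(1, count / total)
}

# minimal stand-in fit carrying only an R^2 (for quality-filter rules)
stub_fit <- function(r2) structure(list(r_squared = r2), class = "spectral_fit")

# noiseless single-channel spectrum fit for feature fixtures
fit_of_spec <- function(spec, settings = fit_settings()) {
  fit_spectrum(make_spectrum(spec), settings)
}
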