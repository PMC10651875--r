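#!/usr/bin/env Rscript
# Statistical batteries per cohort: the eight Holm-corrected paired EEG
# feature tests, the per-band band-power regressions, electrode-wise
# exponent topography tests, and the clinical pre/post comparison.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "config.R"))

cfgs <- study_configs()
clin_rows <- list()
for (nm in names(cfgs)) {
  feats <- read.csv(res_path(paste0("features_", nm, ".csv")))
  bat <- eeg_feature_tests(feats)
  write.csv(bat$tests, res_path(paste0("eeg_tests_", nm, ".csv")),
            row.names = FALSE)
  cat("==", toupper(nm), "EEG feature battery ==\n")
  print(bat$tests[, c("feature", "test", "n", "statistic", "p",
                      "effect", "alpha_adj", "reject_stepdown")],
        digits = 3, row.names = FALSE)

  regs <- list()
  for (b in band_definitions()$name) {
    r <- tryCatch(band_power_regression(feats, b),
                  error = function(e) NULL)
    if (is.null(r)) next
    regs[[b]] <- cbind(band = b, r$terms, adj_r_squared = r$adj_r_squared,
                       f_statistic = r$f_statistic, f_p = r$f_p)
  }
  write.csv(do.call(rbind, regs),
            res_path(paste0("band_regressions_", nm, ".csv")),
            row.names = FALSE)

  fits <- read_fits_csv(res_path(paste0("fits_", nm, ".csv")))
  mats <- exponent_matrices(fits)
  topo <- electrode_topography_tests(mats$pre, mats$post)
  write.csv(topo, res_path(paste0("topography_", nm, ".csv")),
            row.names = FALSE)
  cat(sprintf("%s topography: %d/%d electrodes with uncorrected p < 0.05\n",
              nm, sum(topo$p < 0.05, na.rm = TRUE), nrow(topo)))

  ht <- paired_test(feats$hamd_pre, feats$hamd_post, choice = "wilcoxon")
  clin_rows[[nm]] <- data.frame(
    cohort = nm, n = ht$n, test = ht$test_name, statistic = ht$statistic,
    p = ht$p, cliffs_delta = ht$effect,
    remission_rate = remission_rate(feats$hamd_pre, feats$hamd_post))
}
clin <- do.call(rbind, clin_rows)
write.csv(clin, res_path("clinical_tests.csv"), row.names = FALSE)
cat("== clinical outcomes ==\n")
print(clin, digits = 3, row.names = FALSE)
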