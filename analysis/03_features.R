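#!/usr/bin/env Rscript
# Apply the paired R^2 quality filter and reduce each patient to the
# feature set: electrode-averaged exponent, band powers, aperiodic-adjusted
# oscillation powers, and per-band abundance, at both timepoints.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "config.R"))

cfgs <- study_configs()
for (nm in names(cfgs)) {
  cohort <- make_cohort(cfgs[[nm]])
  fits <- read_fits_csv(res_path(paste0("fits_", nm, ".csv")))
  feats <- cohort_features(cohort, fits)
  write.csv(feats, res_path(paste0("features_", nm, ".csv")),
            row.names = FALSE)
  cat(sprintf("%s: %d/%d patients retained, mean exponent %.2f -> %.2f\n",
              nm, nrow(feats), cfgs[[nm]]$n_patients,
              mean(feats$exponent_pre), mean(feats$exponent_post)))
}
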