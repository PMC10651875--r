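#!/usr/bin/env Rscript
# Simulate one ECT-like and one MST-like pre/post resting-state cohort and
# record the clinical tables and per-patient ground truth.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "config.R"))

cfgs <- study_configs()
for (nm in names(cfgs)) {
  cohort <- make_cohort(cfgs[[nm]])
  print(cohort)
  write.csv(cohort$clinical, res_path(paste0("clinical_", nm, ".csv")),
            row.names = FALSE)
  write.csv(ground_truth_features(cohort),
            res_path(paste0("ground_truth_", nm, ".csv")), row.names = FALSE)
}
jsonlite::write_json(lapply(cfgs, unclass), res_path("cohort_configs.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote clinical tables, ground truth features and configs to results/\n")
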