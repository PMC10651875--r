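# Shared study configuration sourced by every numbered driver.
# Cohort generation is fully determined by these configs, so later stages
# can regenerate the spectra instead of shipping them between scripts.

library(specslow)

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

study_configs <- function() {
  list(
    ect = cohort_config("ECT", n_patients = 22, n_channels = 62, seed = 101),
    mst = cohort_config("MST", n_patients = 22, n_channels = 62, seed = 202))
}

res_path <- function(...) file.path(results_dir, ...)
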