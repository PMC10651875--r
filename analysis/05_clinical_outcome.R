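#!/usr/bin/env Rscript
# Exhaustive search for the EEG feature that best predicts normalized
# post-treatment HAM-D across both cohorts, with baseline severity and
# treatment type always included as fixed effects.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "config.R"))

ect <- read.csv(res_path("features_ect.csv"))
mst <- read.csv(res_path("features_mst.csv"))
tab <- clinical_outcome_table(ect, mst)
sr <- exhaustive_outcome_search(tab)

write.csv(sr$search[order(-sr$search$adj_r_squared), ],
          res_path("outcome_search.csv"), row.names = FALSE)
model <- cbind(sr$result$terms, adj_r_squared = sr$result$adj_r_squared,
               f_statistic = sr$result$f_statistic,
               f_df1 = sr$result$f_df1, f_df2 = sr$result$f_df2,
               f_p = sr$result$f_p, n = sr$n)
write.csv(model, res_path("outcome_model.csv"), row.names = FALSE)

cat(sprintf("selected feature: %s (n = %d)\n",
            paste(sr$selected, collapse = " + "), sr$n))
print(sr$result)
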