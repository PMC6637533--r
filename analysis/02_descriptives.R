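#!/usr/bin/env Rscript
# Stage 2 (Question 1, descriptive): analysis-set preparation and baseline
# biomarker descriptives.
#
# Pools the two placebo arms, applies the pre-specified eosinophil outlier
# rule, derives the analysis groupings, and writes the per-arm biomarker
# summary plus biomarker-by-covariate associations.

library(nbsides)

out <- "results"
trial <- load_trial(file.path(out, "participants.csv"),
                    file.path(out, "visits.csv"))
prepared <- prepare_analysis_set(
  trial, outlier_rules = list(list(biomarker = "eos_cells_ul",
                                   threshold = 4000)))

write.csv(prepared$metadata$exclusions, file.path(out, "exclusions.csv"),
          row.names = FALSE)
bs <- summarize_baseline(prepared)
write.csv(bs, file.path(out, "baseline_summary.csv"), row.names = FALSE)
ca <- covariate_associations(prepared)
write.csv(ca, file.path(out, "covariate_associations.csv"), row.names = FALSE)

cat("Arms after pooling:\n")
print(table(prepared$participants$arm))
cat(sprintf("Excluded %d participant(s) by outlier rule.\n",
            nrow(prepared$metadata$exclusions)))
cat("FeNO by arm (median):\n")
print(bs[bs$biomarker == "feno_ppb", c("arm", "n", "median")])
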