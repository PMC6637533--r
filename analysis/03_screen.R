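#!/usr/bin/env Rscript
# Stage 3 (Question 1, predictive screening): treatment-by-biomarker
# interaction tests, rate curves over each biomarker (linear NB and GAM
# smooth), and quartile / cumulative-cut-off forests.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_common.R"))

prepared <- load_prepared()

it <- interaction_tests(prepared)
write.csv(it, file.path(results_dir, "interaction_tests.csv"),
          row.names = FALSE)
cat("Interaction tests (Wald p per biomarker, joint LRT row first):\n")
print(it, digits = 3)

for (bm in unname(nbsides:::BIOMARKER_COLS)) {
  cl <- effect_curves(prepared, bm, "linear")
  write.csv(cl, file.path(results_dir, paste0("curve_linear_", bm, ".csv")),
            row.names = FALSE)
  cg <- effect_curves(prepared, bm, "gam")
  write.csv(cg, file.path(results_dir, paste0("curve_gam_", bm, ".csv")),
            row.names = FALSE)
  fq <- subgroup_forest(prepared, bm, "quartile")
  write.csv(fq, file.path(results_dir, paste0("forest_quartile_", bm, ".csv")),
            row.names = FALSE)
  fc <- subgroup_forest(prepared, bm, "cumulative")
  write.csv(fc, file.path(results_dir,
                          paste0("forest_cumulative_", bm, ".csv")),
            row.names = FALSE)
}

fq <- read.csv(file.path(results_dir, "forest_quartile_feno_ppb.csv"))
cat("\nFeNO quartile forest (reduction %):\n")
print(fq[, c("label", "n_treated", "n_control", "rate_ratio",
             "reduction_pct")], digits = 3)
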