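#!/usr/bin/env Rscript
# Stage 5 (Question 2, uncertainty): bootstrap distribution of the chosen
# cut-off per biomarker and the permutation null for the best-subgroup
# effect. Reduced resampling scale for a desk run; the production profile
# uses B = 500 and P = 500.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_common.R"))

prepared <- load_prepared()
pars <- sides_params()
B <- 100
P <- 100

bc <- bootstrap_cutoffs(prepared, pars, B = B, seed = 101)
write.csv(bc$draws, file.path(results_dir, "bootstrap_draws.csv"),
          row.names = FALSE)
jsonlite::write_json(
  lapply(bc$biomarkers, function(b)
    list(grid = b$grid, bins_above = b$bins_above,
         bins_below = b$bins_below, n_selected = b$n_selected,
         main_cutoff = b$main_cutoff)),
  file.path(results_dir, "bootstrap_cutoffs.json"),
  auto_unbox = TRUE, digits = NA)
print(bc)

pn <- permutation_null(prepared, pars, P = P, seed = 202)
write.csv(data.frame(draw = seq_len(pn$P),
                     best_reduction = pn$null_reductions),
          file.path(results_dir, "permutation_draws.csv"), row.names = FALSE)
jsonlite::write_json(
  list(P = pn$P, observed = pn$observed, null_median = pn$null_median,
       observed_percentile = pn$observed_percentile,
       n_fallback = pn$n_fallback, n_failed = pn$n_failed),
  file.path(results_dir, "permutation_summary.json"),
  auto_unbox = TRUE, digits = NA)
print(pn)
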