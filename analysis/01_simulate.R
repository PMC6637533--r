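#!/usr/bin/env Rscript
# Stage 1: simulate the study conditions.
#
# Draws one trial from the planted-FeNO-threshold scenario (1,207
# participants, 2:1:2:1 over tralokinumab/placebo Q2W/Q4W arms, five
# correlated log-normal biomarkers calibrated to the observed baseline
# distributions, NB exacerbation counts with a treatment benefit confined
# to the FeNO-high stratum) and writes the analysis files used by the
# later stages, plus a truth sidecar for reference.

library(nbsides)

out <- "results"
dir.create(out, showWarnings = FALSE)
seed <- 202

sc <- scenario_library()$feno_threshold
trial <- simulate_trial(sc, seed = seed)
write_trial(trial, file.path(out, "participants.csv"),
            file.path(out, "visits.csv"))

truth <- attr(trial, "truth")
jsonlite::write_json(
  list(scenario = sc$name, seed = seed,
       true_cutoff = unname(truth$true_cutoffs$feno_ppb[["cutoff"]]),
       true_subgroup_rr = unname(truth$true_cutoffs$feno_ppb[["rr"]]),
       n_in_subgroup = sum(truth$in_subgroup)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "Simulated %d participants; true FeNO cut-off %.1f ppb (subgroup RR %.2f, %d members).\n",
  nrow(trial$participants), truth$true_cutoffs$feno_ppb[["cutoff"]],
  truth$true_cutoffs$feno_ppb[["rr"]], sum(truth$in_subgroup)))
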