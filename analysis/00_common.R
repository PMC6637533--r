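# Shared loader for the analysis stages: re-reads the simulated trial and
# re-derives the analysis set so every stage starts from the same CSVs.
library(nbsides)

results_dir <- "results"

load_prepared <- function() {
  trial <- load_trial(file.path(results_dir, "participants.csv"),
                      file.path(results_dir, "visits.csv"))
  prepare_analysis_set(
    trial, outlier_rules = list(list(biomarker = "eos_cells_ul",
                                     threshold = 4000)))
}
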