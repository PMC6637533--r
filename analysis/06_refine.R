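#!/usr/bin/env Rscript
# Stage 6 (Questions 2-3): cut-off grid scan around the SIDES choice for
# FeNO, and repeated-measures models for the key secondary endpoints in
# the FeNO- and periostin-defined subgroups.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_common.R"))

prepared <- load_prepared()
sides_tab <- read.csv(file.path(results_dir, "sides_subgroups.csv"))

feno_row <- sides_tab[sides_tab$biomarker == "feno_ppb", ][1, ]
grid <- round(feno_row$cutoff) + (-5:5)
scan <- cutoff_scan(prepared, "feno_ppb", grid)
write.csv(scan, file.path(results_dir, "cutoff_scan_feno.csv"),
          row.names = FALSE)
up <- scan[scan$side == "at_or_above" & scan$estimable, ]
best_cut <- up$cutoff[which.min(up$rate_ratio)]
cat(sprintf("Scan around FeNO cut-off %.1f: best >= cut-off is %.0f ppb (RR %.2f).\n",
            feno_row$cutoff, best_cut, min(up$rate_ratio)))
print(scan[, c("cutoff", "side", "n_treated", "n_control", "rate_ratio",
               "p_value")], digits = 3)

secondary <- list()
for (bm in c("feno_ppb", "periostin_ng_ml")) {
  row <- sides_tab[sides_tab$biomarker == bm, ][1, ]
  if (is.na(row$cutoff)) next
  sg <- subgroup(bm, if (bm == "feno_ppb") best_cut else row$cutoff,
                 direction = row$direction,
                 strict = !(bm == "feno_ppb"))  # FeNO side reported as >= cut
  for (e in c("fev1_pct_change", "acq6", "aqlq", "symptom_score")) {
    mm <- mmrm_endpoint(prepared, e, sg)
    for (s in list(mm$inside, mm$outside)) {
      secondary[[length(secondary) + 1L]] <- data.frame(
        biomarker = bm, endpoint = e, side = s$side,
        n_treated = s$n_treated, n_control = s$n_control,
        effect = s$effect, ci_low = s$ci_low, ci_high = s$ci_high,
        p_value = s$p_value, covariance = s$covariance_structure,
        stringsAsFactors = FALSE)
    }
  }
}
sec <- do.call(rbind, secondary)
write.csv(sec, file.path(results_dir, "secondary_endpoints.csv"),
          row.names = FALSE)
cat("\nWeek-52 secondary-endpoint effects by subgroup side:\n")
print(sec[, c("biomarker", "endpoint", "side", "effect", "p_value")],
      digits = 3)
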