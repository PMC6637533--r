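#!/usr/bin/env Rscript
# Stage 7 (decision): comparative summary of the candidate biomarker
# subgroups - prevalence, adjusted AAER reduction, interaction p, count of
# enhanced secondary endpoints, Q4W consistency - and the ranked verdict.
# Question 4 (safety tabulation) is out of scope here: adverse-event
# reporting is descriptive and handled outside this analysis plan.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_common.R"))

prepared <- load_prepared()
sides_tab <- read.csv(file.path(results_dir, "sides_subgroups.csv"))
it <- read.csv(file.path(results_dir, "interaction_tests.csv"))
sec <- read.csv(file.path(results_dir, "secondary_endpoints.csv"))

build_candidate <- function(bm) {
  row <- sides_tab[sides_tab$biomarker == bm, ][1, ]
  sg <- subgroup(bm, row$cutoff, direction = row$direction)
  memb <- in_subgroup(nbsides:::arm_frame(prepared, "q2w"), sg)
  ev <- evaluate_subgroup(prepared, sg)
  ev4 <- evaluate_subgroup(prepared, sg, arm = "q4w")
  side_lab <- format(sg)
  secondary <- lapply(unique(sec$endpoint), function(e) {
    s <- sec[sec$biomarker == bm & sec$endpoint == e &
               !grepl("^not ", sec$side), ][1, ]
    list(inside = list(endpoint = e, effect = s$effect, p_value = s$p_value))
  })
  list(subgroup = sg, n_in = sum(memb, na.rm = TRUE),
       N = sum(!is.na(memb)), effect = ev$subgroup,
       interaction_p = it$q2w_p[it$biomarker == bm],
       secondary = secondary, q4w_effect = ev4$subgroup)
}

cands <- list(feno_ppb = build_candidate("feno_ppb"),
              periostin_ng_ml = build_candidate("periostin_ng_ml"))
ds <- decision_summary(cands)
write.csv(ds, file.path(results_dir, "decision_summary.csv"),
          row.names = FALSE)
cat("Decision summary (ranked):\n")
print(ds[, c("rank", "candidate", "label", "prevalence", "reduction_ci",
             "interaction_p", "n_secondary_enhanced", "q4w_consistent")],
      digits = 3)
cat(sprintf("\nPreferred candidate: %s (%s).\n", ds$candidate[1],
            ds$label[1]))
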