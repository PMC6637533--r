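# Data model, CSV round trip, analysis-set preparation and descriptives.

test_that("write/read round trip is lossless, including missingness", {
  d <- tiny_trial()
  pf <- withr::local_tempfile(fileext = ".csv")
  write_trial(d, pf)
  d2 <- load_trial(pf)
  expect_equal(d2$participants[names(d$participants)], d$participants,
               tolerance = 1e-12)
  expect_identical(is.na(d2$participants$feno_ppb),
                   is.na(d$participants$feno_ppb))
})

test_that("schema and validation errors name the offending column / ids", {
  p <- tiny_participants()
  pf <- withr::local_tempfile(fileext = ".csv")
  write.csv(p[, setdiff(names(p), "followup_years")], pf, row.names = FALSE)
  expect_error(load_trial(pf), "followup_years")

  bad <- p
  bad$followup_years[3] <- -0.1
  expect_error(trial_dataset(bad), bad$participant_id[3])
  bad2 <- p
  bad2$exacerbation_count[5] <- -2
  expect_error(trial_dataset(bad2), "non-negative")
  expect_error(load_trial(tempfile("nope")), "not found")
})

test_that("visit records must reference known participants and be unique", {
  p <- tiny_participants()
  v <- data.frame(participant_id = c("T01", "T01", "ZZZ"),
                  endpoint = "acq6", week = c(12, 24, 12), value = 1:3)
  expect_error(trial_dataset(p, v), "unknown participant")
  v2 <- data.frame(participant_id = c("T01", "T01"), endpoint = "acq6",
                   week = c(12, 12), value = 1:2)
  expect_error(trial_dataset(p, v2), "duplicate")
})

test_that("placebo pooling merges the two placebo arms and nothing else", {
  d <- prepare_analysis_set(tiny_trial())
  tab <- table(d$participants$arm)
  expect_identical(sort(names(tab[tab > 0])),
                   sort(c("placebo", "tralo_q2w", "tralo_q4w")))
  expect_equal(unname(tab[["placebo"]]), 12)  # 6 + 6
  expect_equal(unname(tab[["tralo_q2w"]]), 6)
})

test_that("outlier rules remove and log exactly the matching participants", {
  d0 <- tiny_trial()
  d <- prepare_analysis_set(
    d0, outlier_rules = list(list(biomarker = "eos_cells_ul",
                                  threshold = 4000)))
  ex <- d$metadata$exclusions
  expect_equal(nrow(ex), 2)
  expect_setequal(ex$value, c(7510, 4130))
  expect_equal(nrow(d0$participants) - nrow(d$participants), nrow(ex))
  # retained participants' outcome and exposure untouched
  keep <- d0$participants$participant_id %in% d$participants$participant_id
  expect_equal(d$participants$exacerbation_count,
               d0$participants$exacerbation_count[keep])
  expect_equal(d$participants$followup_years,
               d0$participants$followup_years[keep])
  expect_error(
    prepare_analysis_set(d0, outlier_rules = list(
      list(biomarker = "nope", threshold = 1))),
    "unknown biomarker")
})

test_that("empty rule list changes nothing except pooling and derivations", {
  d0 <- tiny_trial()
  d <- prepare_analysis_set(d0)
  expect_equal(nrow(d$participants), nrow(d0$participants))
  expect_equal(nrow(d$metadata$exclusions), 0)
  expect_equal(d$participants$feno_ppb, d0$participants$feno_ppb)
})

test_that("derived covariates follow the stated conventions", {
  d <- prepare_analysis_set(tiny_trial())
  p <- d$participants
  expect_identical(as.character(p$age_group[p$age_years < 18]),
                   rep("adolescent", sum(p$age_years < 18)))
  med <- median(p$periostin_ng_ml, na.rm = TRUE)
  expect_identical(as.character(p$periostin_group),
                   ifelse(p$periostin_ng_ml > med, "high", "low"))
  expect_identical(levels(p$prior_cat), c("1", "2", ">=3"))
  expect_identical(as.character(p$prior_cat[p$prior_exacerbations >= 3]),
                   rep(">=3", sum(p$prior_exacerbations >= 3)))
})

test_that("baseline summary matches brute-force statistics and Table-1 shape", {
  d <- feno_trial()
  s <- summarize_baseline(d)
  expect_equal(nrow(s), 5 * 3)  # 5 biomarkers x 3 pooled arms
  # brute-force recomputation for one cell
  x <- d$participants$feno_ppb[d$participants$arm == "tralo_q2w"]
  x <- x[!is.na(x)]
  row <- s[s$biomarker == "feno_ppb" & s$arm == "tralo_q2w", ]
  expect_equal(row$n, length(x))
  expect_equal(row$mean, sum(x) / length(x))
  expect_equal(row$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  expect_equal(row$median, median(x))
  expect_equal(c(row$min, row$max), range(x))
  # n values over arms sum to the non-missing count per biomarker
  for (bm in unique(s$biomarker)) {
    expect_equal(sum(s$n[s$biomarker == bm]),
                 sum(!is.na(d$participants[[bm]])))
  }
})

test_that("single-participant summary reports non-computable SD", {
  p <- tiny_participants()[1, ]
  d <- prepare_analysis_set(trial_dataset(p), pool_placebo = TRUE)
  s <- summarize_baseline(d)
  row <- s[s$biomarker == "feno_ppb" & s$n == 1, ]
  expect_equal(row$mean, 20)
  expect_true(is.na(row$sd))
  expect_equal(row$median, 20)
  expect_equal(c(row$min, row$max), c(20, 20))
})

test_that("covariate associations surface a planted regional periostin shift", {
  sc <- scenario_config("shift", n_total = 1500,
                        region_shift = list(biomarker = "periostin_ng_ml",
                                            region = "asia_pacific",
                                            multiplier = 1.6))
  d <- prepare_analysis_set(simulate_trial(sc, seed = 31))
  ca <- covariate_associations(d, "region")
  per <- ca[ca$biomarker == "periostin_ng_ml", ]
  ap <- per$median[per$level == "asia_pacific"]
  expect_true(all(ap > per$median[per$level != "asia_pacific"]))
  # single-level covariate reproduces the overall median
  d$participants$one <- factor("all")
  ca1 <- covariate_associations(d, "one")
  expect_equal(ca1$median[ca1$biomarker == "feno_ppb"],
               median(d$participants$feno_ppb, na.rm = TRUE))
  expect_error(covariate_associations(d, "age_years"), "binning")
})

test_that("subgroup membership partitions non-missing participants", {
  d <- feno_trial()
  sg <- subgroup("feno_ppb", 25)
  memb <- in_subgroup(d, sg)
  comp <- in_subgroup(d, complement_subgroup(sg))
  ok <- !is.na(memb)
  expect_true(all(xor(memb[ok], comp[ok])))
  expect_identical(is.na(memb), is.na(d$participants$feno_ppb))
  expect_match(format(sg), "FeNO > 25 ppb")
  expect_match(format(complement_subgroup(sg)), "FeNO <= 25 ppb")
  both <- intersect_subgroups(sg, subgroup("periostin_ng_ml", 30))
  expect_equal(sum(in_subgroup(d, both), na.rm = TRUE),
               sum(memb & d$participants$periostin_ng_ml > 30, na.rm = TRUE))
})
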