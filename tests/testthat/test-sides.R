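# SIDES search: split grid, criterion formulas, constraints, trace,
# determinism, evaluation, sensitivity.

test_that("candidate splits follow the quantile grid and dedupe ties", {
  p <- sides_params(N_min = 1, n_splits = 50)
  cuts <- candidate_splits(1:100, p)
  expect_equal(length(cuts), 50)
  expect_equal(cuts, unname(quantile(1:100, (1:50) / 51, type = 7)))
  # heavily tied vector: at most the number of distinct values
  tied <- rep(1:10, each = 30)
  expect_lte(length(candidate_splits(tied, p)), 10)
  expect_equal(candidate_splits(rep(3, 50), p), numeric(0))
  # N_min floor: both children must reach it
  p60 <- sides_params(N_min = 60, n_splits = 50)
  cuts60 <- candidate_splits(1:200, p60)
  expect_true(all(vapply(cuts60, function(cc)
    sum(1:200 > cc) >= 60 && sum(1:200 <= cc) >= 60, logical(1))))
})

test_that("criterion formulas match their analytic forms", {
  # symmetric children: differential criterion is powerless
  expect_equal(nbsides:::criterion_p(1.3, 1.3, 1), 1)
  # |z1 - z2| = 1.96 * sqrt(2) -> p = 0.0500 (4 decimals)
  expect_equal(round(nbsides:::criterion_p(1.96 * sqrt(2), 0, 1), 4), 0.05)
  # criterion 2 analytic form
  expect_equal(nbsides:::criterion_p(2, 0.5, 2),
               2 * min(1 - pnorm(2), 1 - pnorm(0.5)))
  # criterion 3 = criterion 1 gated on one-sided benefit of the better child
  expect_equal(nbsides:::criterion_p(3, -1, 3),
               nbsides:::criterion_p(3, -1, 1))
  expect_equal(nbsides:::criterion_p(1, -2.5, 3), 1)
})

test_that("split scores carry benefit z and reject degenerate children", {
  d <- feno_trial()
  s <- split_score(d, "feno_ppb", 25)
  expect_true(s$ok)
  expect_equal(s$N_s, if (s$better_child == "above") s$n_above else s$n_below)
  expect_true(s$criterion_p >= 0 && s$criterion_p <= 1)
  # planted benefit above 25: the above child should carry positive z
  expect_gt(s$z_above, s$z_below)
  s2 <- split_score(d, "feno_ppb", 1e6)
  expect_false(s2$ok)
  expect_match(s2$reason, "empty child")
})

test_that("criterion-1 p-values are uniform under the null", {
  # fresh null trial per draw; one random admissible split each
  ps <- vapply(1:120, function(i) {
    d <- prepare_analysis_set(simulate_trial(
      scenario_config("null", n_total = 400), seed = 5200 + i))
    df <- nbsides:::arm_frame(d, "q2w")
    set.seed(i)
    cc <- quantile(df$feno_ppb, runif(1, .2, .8), na.rm = TRUE)
    split_score(d, "feno_ppb", cc)$criterion_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("depth-1 search returns single-covariate subgroups meeting constraints", {
  d <- feno_trial()
  pars <- sides_params()
  res <- sides_run(d, pars)
  sg <- res$subgroups
  expect_true(all(sg$depth == 1))
  expect_true(all(sg$N_s >= pars$N_min))
  expect_true(all(sg$prevalence >= pars$min_prevalence))
  expect_true(all(diff(sg$criterion_p) >= 0))
  # bit-identical re-run: the search is deterministic given data and params
  res2 <- sides_run(d, pars)
  expect_identical(res$subgroups, res2$subgroups)
  expect_identical(res$trace, res2$trace)
})

test_that("the trace records every candidate cut-off exactly once per node", {
  d <- feno_trial()
  pars <- sides_params()
  res <- sides_run(d, pars)
  df <- nbsides:::arm_frame(d, "q2w")
  for (cv in pars$search_covariates) {
    cuts <- candidate_splits(df[[cv]], pars)
    tr <- res$trace[res$trace$biomarker == cv &
                      res$trace$status %in% c("scored", "empty child",
                                              "child lacks an arm",
                                              "child fit non-convergent"), ]
    expect_equal(sort(tr$cutoff), sort(cuts))
    expect_false(anyDuplicated(tr$cutoff) > 0)
  }
})

test_that("sides_run equals exhaustive enumeration on a 3-cut-off toy", {
  d <- feno_trial()
  # a toy covariate with 4 distinct values -> 3 possible cut-offs
  set.seed(2)
  d$participants$toy <- sample(c(1, 2, 3, 4), nrow(d$participants),
                               replace = TRUE)
  pars <- sides_params(N_min = 10, n_splits = 50,
                       search_covariates = "toy", min_prevalence = 0)
  res <- sides_run(d, pars)
  # oracle: enumerate the three splits by hand
  scores <- lapply(c(1, 2, 3), function(cc) split_score(d, "toy", cc))
  ok <- Filter(function(s) s$ok, scores)
  ps <- vapply(ok, `[[`, 0, "criterion_p")
  best <- ok[[which.min(ps)]]
  expect_equal(res$subgroups$cutoff[1], best$cutoff)
  expect_equal(res$subgroups$criterion_p[1], best$criterion_p)
  expect_equal(res$subgroups$direction[1], best$better_child)
})

test_that("deeper searches respect L and the continuation filter", {
  d <- feno_trial()
  pars <- sides_params(L = 2, M = 2, N_min = 40, min_prevalence = 0.1)
  res <- sides_run(d, pars)
  sg <- res$subgroups
  expect_true(all(sg$depth <= 2))
  if (any(sg$depth == 2)) {
    # depth-2 labels are compound
    expect_true(all(grepl("&", sg$label[sg$depth == 2])))
  }
  # gamma = tiny: continuation rejects every depth-2 child
  pars2 <- sides_params(L = 2, M = 2, N_min = 40, min_prevalence = 0.1,
                        gamma = 1e-12)
  res2 <- sides_run(d, pars2)
  expect_true(all(res2$subgroups$depth == 1))
})

test_that("selection threshold filters reported subgroups", {
  d <- feno_trial()
  res0 <- sides_run(d, sides_params(selection_threshold = 0))
  res35 <- sides_run(d, sides_params(selection_threshold = 35))
  expect_true(all(res35$subgroups$reduction_pct >= 35))
  expect_lte(nrow(res35$subgroups), nrow(res0$subgroups))
})

test_that("whole-population subgroup evaluation equals the all-comers fit", {
  d <- feno_trial()
  sg <- subgroup("feno_ppb", -1)  # everyone (non-missing) is above
  ev <- evaluate_subgroup(d, sg)
  df <- nbsides:::arm_frame(d, "q2w")
  df <- df[!is.na(df$feno_ppb), ]
  ac <- effect_from_fit(
    fit_nb(df, exacerbation_count ~ treat + region + age_years + prior_cat),
    "treattralo")
  expect_equal(ev$subgroup$rate_ratio, ac$rate_ratio, tolerance = 1e-8)
  expect_false(ev$complementary$estimable)
})

test_that("subgroup evaluation equals a direct oracle refit on subset rows", {
  d <- feno_trial()
  sg <- subgroup("feno_ppb", 25)
  ev <- evaluate_subgroup(d, sg)
  df <- nbsides:::arm_frame(d, "q2w")
  sub <- df[!is.na(df$feno_ppb) & df$feno_ppb > 25, ]
  oracle <- effect_from_fit(
    fit_nb(sub, exacerbation_count ~ treat + region + age_years + prior_cat),
    "treattralo")
  expect_equal(ev$subgroup$rate_ratio, oracle$rate_ratio, tolerance = 1e-8)
  expect_match(ev$subgroup$label, "FeNO > 25")
  expect_match(ev$complementary$label, "FeNO <= 25")
})

test_that("sensitivity re-runs tabulate variants; relaxing constraints widens the search", {
  d <- feno_trial()
  base <- sides_params()
  tab0 <- sensitivity_reruns(d, base)
  expect_equal(nrow(tab0), 1)
  expect_equal(tab0$variant, "base")
  tab <- sensitivity_reruns(d, base, variants = list(
    loose = list(min_prevalence = 0, N_min = 30),
    crit2 = list(criterion = 2)))
  expect_equal(tab$variant, c("base", "loose", "crit2"))
  # dropping the prevalence floor can only widen the admissible subgroup set
  res_base <- sides_run(d, base)
  res_loose <- sides_run(d, sides_params(min_prevalence = 0))
  expect_true(all(res_base$subgroups$label %in% res_loose$subgroups$label))
  expect_gte(nrow(res_loose$subgroups), nrow(res_base$subgroups))
})
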