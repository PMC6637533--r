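# Cut-off scan, repeated-measures endpoint models, decision summary.

test_that("scan table has two covering rows per cut-off", {
  d <- feno_trial()
  grid <- seq(20, 30, by = 2)
  tab <- cutoff_scan(d, "feno_ppb", grid)
  expect_equal(nrow(tab), 2 * length(grid))
  df <- nbsides:::arm_frame(d, "q2w")
  n_bm <- sum(!is.na(df$feno_ppb))
  for (cc in grid) {
    rows <- tab[tab$cutoff == cc, ]
    expect_setequal(rows$side, c("at_or_above", "below"))
    # the two sides cover all non-missing participants exactly once
    expect_equal(sum(rows$n_treated) + sum(rows$n_control), n_bm)
  }
  expect_error(cutoff_scan(d, "feno_ppb", numeric(0)), "non-empty")
})

test_that("a cut-off below the observed minimum degrades gracefully", {
  d <- feno_trial()
  tab <- cutoff_scan(d, "feno_ppb", -5)
  up <- tab[tab$side == "at_or_above", ]
  lo <- tab[tab$side == "below", ]
  expect_true(up$estimable)
  expect_false(lo$estimable)
  df <- nbsides:::arm_frame(d, "q2w")
  df <- df[!is.na(df$feno_ppb), ]
  ac <- effect_from_fit(
    fit_nb(df, exacerbation_count ~ treat + region + age_group +
             periostin_group + prior_cat), "treattralo")
  expect_equal(up$rate_ratio, ac$rate_ratio, tolerance = 1e-8)
})

test_that("scan at a chosen cut-off reproduces the subgroup evaluation", {
  # same covariate set, fixed Poisson dispersion: the saturated
  # treatment-by-side model separates into the per-side fits
  d <- feno_trial()
  cc <- 25
  tab <- cutoff_scan(d, "feno_ppb", cc, covariates = character(0),
                     dispersion = 0)
  ev <- evaluate_subgroup(d, subgroup("feno_ppb", cc, strict = FALSE),
                          covariates = character(0), dispersion = 0)
  up <- tab[tab$side == "at_or_above", ]
  expect_equal(log(up$rate_ratio), log(ev$subgroup$rate_ratio),
               tolerance = 1e-6)
  lo <- tab[tab$side == "below", ]
  expect_equal(log(lo$rate_ratio), log(ev$complementary$rate_ratio),
               tolerance = 1e-6)
})

test_that("scan localises a planted threshold near the truth", {
  d <- feno_trial()
  cc <- unname(d$metadata$truth$true_cutoffs$feno_ppb[["cutoff"]])
  grid <- round(cc) + (-4:4)
  tab <- cutoff_scan(d, "feno_ppb", grid)
  up <- tab[tab$side == "at_or_above" & tab$estimable, ]
  best <- up$cutoff[which.min(up$rate_ratio)]
  expect_lte(abs(best - cc), 5)
  # reductions above the cut exceed reductions below it throughout
  lo <- tab[tab$side == "below" & tab$estimable, ]
  expect_gt(mean(up$reduction_pct), mean(lo$reduction_pct))
})

test_that("compound-symmetric MMRM agrees with a random-intercept oracle", {
  sc <- scenario_config("mm", n_total = 300,
                        endpoint_effects = list(acq6 = list(overall = -0.4)))
  d <- prepare_analysis_set(simulate_trial(sc, seed = 61))
  sg <- subgroup("feno_ppb", median(d$participants$feno_ppb, na.rm = TRUE))
  mm <- mmrm_endpoint(d, "acq6", sg, covariance = "compound_symmetric")
  # oracle: random-intercept mixed model, an equivalent parameterisation
  df <- nbsides:::arm_frame(d, "q2w")
  memb <- in_subgroup(df, sg)
  df <- df[!is.na(memb), ]
  df$bm_group <- factor(ifelse(memb[!is.na(memb)], "inside", "outside"),
                        levels = c("outside", "inside"))
  v <- d$visits[d$visits$endpoint == "acq6", ]
  m <- merge(v, df, by = "participant_id")
  m$change <- m$value - m$baseline_acq6
  m <- m[!is.na(m$change), ]
  m$visit_f <- factor(m$week)
  lf <- nlme::lme(change ~ baseline_acq6 + treat + region + age_group +
                    periostin_group + prior_cat + bm_group + visit_f +
                    treat:visit_f + treat:bm_group,
                  random = ~ 1 | participant_id, data = m, method = "ML",
                  na.action = na.omit)
  cf <- nlme::fixef(lf)
  eff_in <- cf[["treattralo"]] + cf[["treattralo:visit_f52"]] +
    cf[["treattralo:bm_groupinside"]]
  expect_equal(mm$inside$effect, unname(eff_in), tolerance = 1e-4)
})

test_that("MMRM recovers effects and honours the covariance conventions", {
  sc <- scenario_config("mm2", n_total = 500,
                        endpoint_effects = list(
                          fev1_pct_change = list(overall = 10)))
  d <- prepare_analysis_set(simulate_trial(sc, seed = 62))
  sg <- subgroup("feno_ppb", median(d$participants$feno_ppb, na.rm = TRUE))
  mm <- mmrm_endpoint(d, "fev1_pct_change", sg)
  expect_equal(mm$inside$covariance_structure, "unstructured")
  expect_lt(abs(mm$inside$effect - 10), 6)   # single-trial CI-scale check
  expect_lt(abs(mm$outside$effect - 10), 6)
  mm2 <- mmrm_endpoint(d, "acq6", sg)
  expect_equal(mm2$inside$covariance_structure, "compound_symmetric")
  expect_error(mmrm_endpoint(d, "nope", sg), "endpoint")
  # n bookkeeping: per-side counts bounded by arm sizes
  df <- nbsides:::arm_frame(d, "q2w")
  expect_lte(mm$inside$n_treated + mm$outside$n_treated,
             sum(df$treat == "tralo"))
})

test_that("decision summary ranks, flags and stays a pure function", {
  eff <- nbsides:::effect_estimate(0.56, 0.34, 0.94, 0.028,
                                   n_treated = 97, n_control = 102)
  mk <- function(ip, nsig, red_eff) {
    sec <- lapply(c("fev1_pct_change", "acq6", "aqlq"), function(e) {
      hit <- nsig > 0
      nsig <<- nsig - 1
      dirn <- c(fev1_pct_change = 1, acq6 = -1, aqlq = 1)[[e]]
      list(inside = list(endpoint = e,
                         effect = if (hit) dirn * 5 else dirn * 0.1,
                         p_value = if (hit) 0.001 else 0.6))
    })
    list(subgroup = subgroup("feno_ppb", 37, strict = FALSE),
         n_in = 285, N = 1202, effect = red_eff, interaction_p = ip,
         secondary = sec)
  }
  cands <- list(feno = mk(0.038, 3, eff),
                periostin = mk(0.478, 0,
                               nbsides:::effect_estimate(0.69, 0.46, 1.04,
                                                         0.08)))
  ds <- decision_summary(cands)
  expect_equal(ds$candidate[1], "feno")
  expect_equal(ds$prevalence[1], "23.7 (285/1202)")
  expect_equal(ds$reduction_ci[1], "44 (6, 66)")
  expect_true(ds$interaction_nominal[1])
  expect_false(ds$interaction_nominal[2])
  expect_equal(ds$n_secondary_enhanced, c(3L, 0L))
  # identical candidates -> identical rows (bar the name)
  ds2 <- decision_summary(list(a = cands$feno, b = cands$feno))
  expect_equal(ds2$reduction_ci[1], ds2$reduction_ci[2])
  expect_equal(ds2$n_secondary_enhanced[1], ds2$n_secondary_enhanced[2])
  # missing inputs are flagged, never silently blank
  ds3 <- decision_summary(list(x = list(
    subgroup = subgroup("feno_ppb", 37), n_in = 100, N = 400,
    effect = NULL, interaction_p = NULL, secondary = NULL)))
  expect_match(ds3$incomplete, "effect")
  expect_match(ds3$incomplete, "secondary")
})

test_that("a planted FeNO-only scenario ranks FeNO above periostin end to end", {
  d <- feno_trial()
  res <- sides_run(d, sides_params())
  build <- function(bm) {
    row <- res$subgroups[res$subgroups$biomarker == bm, ][1, ]
    sg <- subgroup(bm, row$cutoff, direction = row$direction)
    memb <- in_subgroup(nbsides:::arm_frame(d, "q2w"), sg)
    ev <- evaluate_subgroup(d, sg)
    it <- interaction_tests(d, biomarkers = bm, arms = "q2w", scale = "log")
    sec <- lapply(c("fev1_pct_change", "acq6"), function(e)
      mmrm_endpoint(d, e, sg))
    list(subgroup = sg, n_in = sum(memb, na.rm = TRUE),
         N = sum(!is.na(memb)), effect = ev$subgroup,
         interaction_p = it$q2w_p[it$biomarker == bm], secondary = sec)
  }
  ds <- decision_summary(list(feno_ppb = build("feno_ppb"),
                              periostin_ng_ml = build("periostin_ng_ml")))
  expect_equal(ds$candidate[1], "feno_ppb")
})
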