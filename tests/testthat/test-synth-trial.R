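# Synthetic trial generator: allocation, calibration, planted effects,
# reproducibility and the truth record.

test_that("largest-remainder allocation hits the 2:1:2:1 arm sizes", {
  cnt <- nbsides:::allocate_arms(1207, c(tralo_q2w = 2, placebo_q2w = 1,
                                         tralo_q4w = 2, placebo_q4w = 1))
  expect_equal(sum(cnt), 1207)
  expect_setequal(unname(cnt), c(403, 402, 201, 201))
  # each arm within 1 of the exact proportional share
  expect_true(all(abs(cnt - 1207 * c(2, 1, 2, 1) / 6) < 1))
  d <- simulate_trial(scenario_config(n_total = 1207), seed = 1)
  expect_equal(sum(table(d$participants$arm)), 1207)
  expect_setequal(unname(table(d$participants$arm)), c(403, 402, 201, 201))
})

test_that("the same seed reproduces the dataset exactly", {
  sc <- scenario_library(n_total = 300)$feno_threshold
  d1 <- simulate_trial(sc, seed = 5)
  d2 <- simulate_trial(sc, seed = 5)
  expect_identical(d1$participants, d2$participants)
  expect_identical(d1$visits, d2$visits)
  d3 <- simulate_trial(sc, seed = 6)
  expect_false(identical(d1$participants$exacerbation_count,
                         d3$participants$exacerbation_count))
})

test_that("null Poisson limit: per-arm mean counts match the placebo rate", {
  sc <- scenario_config("poisson", n_total = 10000, dispersion_k = 0,
                        dropout_rate = 0, prior_exac_coef = 0,
                        biomarker_missing_rate = 0)
  d <- simulate_trial(sc, seed = 20)
  p <- d$participants
  expect_true(all(p$followup_years == 1))
  for (a in unique(p$arm)) {
    m <- mean(p$exacerbation_count[p$arm == a])
    n <- sum(p$arm == a)
    # CLT bound: 4 SE of a Poisson mean
    expect_lt(abs(m - sc$placebo_aaer), 4 * sqrt(sc$placebo_aaer / n))
  }
})

test_that("log-normal moment matching follows the closed form", {
  marg <- list(median = 20.3, mean = 30)
  pr <- nbsides:::lnorm_params(marg)
  # independent moment oracle: lognormal mean and median from (mu, sigma)
  expect_equal(exp(pr[["mu"]]), 20.3)
  expect_equal(exp(pr[["mu"]] + pr[["sigma"]]^2 / 2), 30)
  expect_error(scenario_config(biomarker_marginals = list(
    feno_ppb = c(median = 30, mean = 20))), "calibration error")
})

test_that("generated biomarker marginals converge to their targets", {
  sc <- scenario_config("big", n_total = 50000, biomarker_missing_rate = 0)
  d <- simulate_trial(sc, seed = 404)
  p <- d$participants
  for (bm in names(sc$biomarker_marginals)) {
    tgt <- sc$biomarker_marginals[[bm]]
    x <- p[[bm]]
    # medians: CLT bound on the sample quantile; means: 5 SE
    expect_lt(abs(median(x) - tgt[["median"]]) / tgt[["median"]], 0.03)
    expect_lt(abs(mean(x) - tgt[["mean"]]), 5 * sd(x) / sqrt(length(x)))
  }
  # log-scale correlation near the copula target for the correlated trio
  lc <- cor(log(p$feno_ppb), log(p$periostin_ng_ml))
  expect_lt(abs(lc - 0.3), 0.03)
  expect_lt(abs(cor(log(p$feno_ppb), log(p$ige_iu_ml))), 0.03)
})

test_that("planted threshold interaction yields the planted rate ratio", {
  sc <- scenario_config("planted", n_total = 20000,
                        interaction = list(biomarker = "feno_ppb",
                                           type = "threshold",
                                           cutoff_quantile = 0.75, rr = 0.5),
                        all_comers_rr = 0.9, biomarker_missing_rate = 0)
  d <- simulate_trial(sc, seed = 8)
  tr <- attr(d, "truth")
  p <- d$participants
  # oracle: rates computed directly from the truth record
  aaer <- function(rows) sum(p$exacerbation_count[rows]) /
    sum(p$followup_years[rows])
  act <- p$arm == "tralo_q2w"
  plc <- p$arm %in% c("placebo_q2w", "placebo_q4w")
  rr_in <- aaer(tr$in_subgroup & act) / aaer(tr$in_subgroup & plc)
  expect_lt(abs(rr_in - 0.9 * 0.5), 0.06)
  # true cut-off is the stated theoretical quantile
  pr <- nbsides:::lnorm_params(sc$biomarker_marginals$feno_ppb)
  expect_equal(unname(tr$true_cutoffs$feno_ppb[["cutoff"]]),
               qlnorm(0.75, pr[["mu"]], pr[["sigma"]]))
})

test_that("truth record is sufficient to recompute every expected rate", {
  sc <- scenario_library(n_total = 400)$feno_threshold
  d <- simulate_trial(sc, seed = 17)
  tr <- attr(d, "truth")
  cfg <- tr$config
  lp <- log(cfg$placebo_aaer) +
    as.vector(tr$z_std %*% cfg$prognostic_coefs[colnames(tr$z_std)]) +
    cfg$prior_exac_coef * (pmin(d$participants$prior_exacerbations, 3) - 1)
  lp[tr$arm == "tralo_q2w"] <- lp[tr$arm == "tralo_q2w"] + log(cfg$all_comers_rr)
  lp[tr$arm == "tralo_q4w"] <- lp[tr$arm == "tralo_q4w"] + log(cfg$q4w_rr)
  act <- tr$arm %in% c("tralo_q2w", "tralo_q4w")
  ia <- cfg$interaction[[1]]
  lp[act & tr$in_subgroup] <- lp[act & tr$in_subgroup] + log(ia$rr)
  expect_equal(exp(lp), tr$expected_rate, tolerance = 1e-12)
})

test_that("scenario library covers the stated axes with calibrated marginals", {
  lib <- scenario_library(n_total = 200)
  expect_true(all(c("global_null", "prognostic_only", "all_comers_only",
                    "feno_threshold", "feno_smooth", "feno_periostin") %in%
                    names(lib)))
  gn <- lib$global_null
  expect_true(all(gn$prognostic_coefs == 0))
  expect_equal(gn$all_comers_rr, 1)
  expect_null(gn$interaction)
  for (sc in lib) {
    expect_equal(sc$biomarker_marginals$feno_ppb[["median"]], 20.3)
    expect_equal(sc$biomarker_marginals$eos_cells_ul[["median"]], 200)
  }
  expect_equal(length(lib$feno_periostin$interaction), 2)
})

test_that("dropout truncates follow-up and makes endpoint missingness monotone", {
  sc <- scenario_config("drop", n_total = 2000, dropout_rate = 0.3)
  d <- simulate_trial(sc, seed = 55)
  p <- d$participants
  expect_lt(abs(mean(p$followup_years < 1) - 0.3), 0.04)
  v <- d$visits[d$visits$endpoint == "acq6", ]
  m <- merge(v, p[, c("participant_id", "followup_years")])
  # missing exactly after dropout
  expect_true(all(is.na(m$value[m$week / 52 > m$followup_years + 1e-9])))
  early <- m$week / 52 <= m$followup_years
  expect_true(!anyNA(m$value[early]))
})
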