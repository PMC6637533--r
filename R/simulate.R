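# Synthetic biomarker-stratified exacerbation trials.
#
# The generator emulates the statistical structure the analysis plan assumes:
# 2:1:2:1 allocation over four arms, five right-skewed correlated baseline
# biomarkers (log-normal marginals moment-matched to target median/mean,
# correlation imposed through a Gaussian copula on the logs), baseline
# covariates, ~52-week follow-up with independent exponential dropout,
# negative-binomial exacerbation counts whose log rate carries prognostic
# biomarker terms, an arm effect and an optional treatment-by-biomarker
# interaction (threshold or linear-in-log), and visit-indexed secondary
# endpoints with compound-symmetric within-subject correlation.

default_biomarker_marginals <- function() {
  # Calibrated to the observed baseline distributions: median and mean per
  # biomarker on the raw scale.
  list(
    feno_ppb        = c(median = 20.3, mean = 30),
    periostin_ng_ml = c(median = 23.0, mean = 26.0),
    eos_cells_ul    = c(median = 200, mean = 290),
    dpp4_ng_ml      = c(median = 250, mean = 264),
    ige_iu_ml       = c(median = 150, mean = 432)
  )
}

default_biomarker_corr <- function(rho = 0.3) {
  bm <- unname(BIOMARKER_COLS)
  R <- diag(5)
  dimnames(R) <- list(bm, bm)
  trio <- c("feno_ppb", "periostin_ng_ml", "eos_cells_ul")
  R[trio, trio] <- rho
  diag(R) <- 1
  R
}

default_endpoint_params <- function() {
  # baseline mean/SD (scores; fev1 baseline is % predicted, kept separate),
  # placebo drift over 52 weeks, between-subject SD, residual SD.
  list(
    fev1_pct_change = list(baseline_mean = NA, baseline_sd = NA,
                           drift = 2, sd_subj = 12, sd_eps = 10),
    acq6            = list(baseline_mean = 2.8, baseline_sd = 0.8,
                           drift = -0.3, sd_subj = 0.6, sd_eps = 0.5),
    aqlq            = list(baseline_mean = 4.0, baseline_sd = 1.0,
                           drift = 0.2, sd_subj = 0.7, sd_eps = 0.5),
    symptom_score   = list(baseline_mean = 1.5, baseline_sd = 0.6,
                           drift = -0.1, sd_subj = 0.45, sd_eps = 0.4)
  )
}

#' Define a simulation scenario
#'
#' Every generative parameter of the simulator in one configuration object:
#' arm allocation, placebo annualised exacerbation rate, overall (all-comers)
#' and Q4W rate ratios, NB dispersion (variance mu + k mu^2), biomarker
#' marginals and log-scale correlation, prognostic slopes per standardised
#' log-biomarker, an optional planted treatment-by-biomarker interaction,
#' covariate category probabilities, dropout, and per-endpoint longitudinal
#' effects. The returned object is also the truth record against which
#' operating characteristics are judged.
#'
#' @param name scenario label.
#' @param n_total number randomised.
#' @param allocation_ratio integer 4-vector (tralo_q2w, placebo_q2w,
#'   tralo_q4w, placebo_q4w); participants are allocated by largest-remainder
#'   rounding then label shuffling.
#' @param placebo_aaer placebo annualised exacerbation rate (events/year).
#' @param all_comers_rr rate ratio tralo Q2W vs placebo, whole population.
#' @param q4w_rr rate ratio tralo Q4W vs placebo.
#' @param dispersion_k NB dispersion k >= 0; k = 0 gives Poisson counts.
#' @param biomarker_marginals list of `c(median =, mean =)` per biomarker.
#' @param biomarker_corr 5x5 positive semi-definite log-scale correlation.
#' @param prognostic_coefs named log-rate slopes per standardised
#'   log-biomarker.
#' @param prior_exac_coef log-rate increment per prior-exacerbation category
#'   step above 1.
#' @param interaction optional planted predictive effect:
#'   `list(biomarker =, type = "threshold", cutoff_quantile =, rr =)` applies
#'   the extra rate ratio `rr` to treated participants above the biomarker's
#'   theoretical `cutoff_quantile`; `type = "linear"` uses
#'   `list(..., slope =)`, a treated-only log-rate slope per standardised
#'   log-biomarker. A list of such specs plants several interactions.
#' @param region_probs,adolescent_prob,prior_probs covariate generators.
#' @param region_shift optional `list(biomarker =, region =, multiplier =)`
#'   multiplicative biomarker shift in one region.
#' @param dropout_rate fraction dropped out by Week 52 (exponential,
#'   outcome-independent; follow-up = min(1 year, dropout time)).
#' @param biomarker_missing_rate per-biomarker missingness probability.
#' @param visit_weeks secondary-endpoint visit schedule.
#' @param endpoint_params per-endpoint baseline/variance parameters.
#' @param endpoint_effects per-endpoint
#'   `list(overall =, subgroup_bonus =)` Week-52 treatment effects (the bonus
#'   applies inside the planted interaction subgroup); effects ramp linearly
#'   in week/52.
#' @param seed default seed used by [simulate_trial()].
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom",
                            n_total = 1207,
                            allocation_ratio = c(tralo_q2w = 2, placebo_q2w = 1,
                                                 tralo_q4w = 2, placebo_q4w = 1),
                            placebo_aaer = 0.8,
                            all_comers_rr = 1.0,
                            q4w_rr = 1.0,
                            dispersion_k = 1.0,
                            biomarker_marginals = default_biomarker_marginals(),
                            biomarker_corr = default_biomarker_corr(),
                            prognostic_coefs = NULL,
                            prior_exac_coef = 0.15,
                            interaction = NULL,
                            region_probs = c(europe = 0.45, americas = 0.30,
                                             asia_pacific = 0.25),
                            region_shift = NULL,
                            adolescent_prob = 0.03,
                            prior_probs = c(`1` = 0.5, `2` = 0.3,
                                            `3` = 0.15, `4` = 0.05),
                            dropout_rate = 0.10,
                            biomarker_missing_rate = 0.01,
                            visit_weeks = c(4, 12, 24, 36, 52),
                            endpoint_params = default_endpoint_params(),
                            endpoint_effects = NULL,
                            seed = NULL) {
  if (length(allocation_ratio) != 4 || any(allocation_ratio < 1))
    stop("configuration error: allocation_ratio must be 4 entries, each >= 1",
         call. = FALSE)
  ev <- eigen(biomarker_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("configuration error: biomarker_corr is not positive semi-definite",
         call. = FALSE)
  for (bm in names(biomarker_marginals)) {
    m <- biomarker_marginals[[bm]]
    if (m[["mean"]] <= m[["median"]] * (1 + 1e-9))
      stop("calibration error: mean must exceed median for log-normal ",
           "marginal of ", bm, call. = FALSE)
  }
  zero <- setNames(rep(0, 5), unname(BIOMARKER_COLS))
  pc <- zero
  if (!is.null(prognostic_coefs)) pc[names(prognostic_coefs)] <- prognostic_coefs
  if (!is.null(interaction) && !is.null(interaction$biomarker))
    interaction <- list(interaction)
  for (ia in interaction) {
    if (!is.null(ia$rr) && ia$rr <= 0)
      stop("configuration error: interaction rr must be positive", call. = FALSE)
  }
  eff <- lapply(ENDPOINTS, function(e) list(overall = 0, subgroup_bonus = 0))
  names(eff) <- ENDPOINTS
  for (e in names(endpoint_effects %||% list())) {
    eff[[e]]$overall <- endpoint_effects[[e]]$overall %||% 0
    eff[[e]]$subgroup_bonus <- endpoint_effects[[e]]$subgroup_bonus %||% 0
  }
  structure(list(
    name = name, n_total = n_total, allocation_ratio = allocation_ratio,
    placebo_aaer = placebo_aaer, all_comers_rr = all_comers_rr,
    q4w_rr = q4w_rr, dispersion_k = dispersion_k,
    biomarker_marginals = biomarker_marginals, biomarker_corr = biomarker_corr,
    prognostic_coefs = pc, prior_exac_coef = prior_exac_coef,
    interaction = interaction, region_probs = region_probs,
    region_shift = region_shift, adolescent_prob = adolescent_prob,
    prior_probs = prior_probs, dropout_rate = dropout_rate,
    biomarker_missing_rate = biomarker_missing_rate,
    visit_weeks = visit_weeks, endpoint_params = endpoint_params,
    endpoint_effects = eff, seed = seed), class = "scenario_config")
}

# log-normal parameters matched to a (median, mean) pair:
# mu = log(median); sigma^2 = 2 log(mean/median).
lnorm_params <- function(marginal) {
  mu <- log(marginal[["median"]])
  sigma2 <- 2 * log(marginal[["mean"]] / marginal[["median"]])
  c(mu = mu, sigma = sqrt(sigma2))
}

# Largest-remainder allocation of n into parts proportional to ratio.
allocate_arms <- function(n, ratio) {
  exact <- n * ratio / sum(ratio)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  setNames(as.integer(base), names(ratio))
}

#' Simulate one trial from a scenario
#'
#' Draws a complete trial (participants and visit records) plus a truth
#' record sufficient to recompute every participant's expected event rate:
#' the realised linear predictor, the planted subgroup membership, the
#' theoretical interaction cut-off(s) and the full configuration.
#'
#' @param config a [scenario_config()].
#' @param seed seed; defaults to `config$seed`. The same seed yields a
#'   byte-identical dataset.
#' @return a [trial_dataset()]; the truth record is in
#'   `attr(, "truth")` and `metadata$truth`.
#' @export
simulate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_total
  counts <- allocate_arms(n, config$allocation_ratio)
  arm <- sample(rep(names(counts), counts))

  bm_cols <- unname(BIOMARKER_COLS)
  # Gaussian copula on logs: z is the standardised log-biomarker matrix.
  Rchol <- chol(config$biomarker_corr[bm_cols, bm_cols] +
                  diag(1e-10, 5))
  z <- matrix(rnorm(n * 5), n, 5) %*% Rchol
  colnames(z) <- bm_cols
  bm <- matrix(NA_real_, n, 5, dimnames = list(NULL, bm_cols))
  for (b in bm_cols) {
    pr <- lnorm_params(config$biomarker_marginals[[b]])
    bm[, b] <- exp(pr[["mu"]] + pr[["sigma"]] * z[, b])
  }

  region <- sample(names(config$region_probs), n, replace = TRUE,
                   prob = config$region_probs)
  if (!is.null(config$region_shift)) {
    rs <- config$region_shift
    hit <- region == rs$region
    bm[hit, rs$biomarker] <- bm[hit, rs$biomarker] * rs$multiplier
  }

  adol <- runif(n) < config$adolescent_prob
  age <- ifelse(adol, runif(n, 12, 18),
                pmin(pmax(rnorm(n, 50, 13), 18), 80))
  prior <- as.integer(sample(names(config$prior_probs), n, replace = TRUE,
                             prob = config$prior_probs))

  lambda <- -log(1 - config$dropout_rate)
  t_drop <- if (lambda > 0) rexp(n, lambda) else rep(Inf, n)
  followup <- pmin(1, t_drop)
  # guard against numerically zero exposures
  followup <- pmax(followup, 1 / 365)

  # log-rate: baseline + prognostic (on standardised logs) + prior history +
  # arm effect + planted interaction(s)
  lp <- log(config$placebo_aaer) +
    as.vector(z %*% config$prognostic_coefs[bm_cols]) +
    config$prior_exac_coef * (pmin(prior, 3) - 1)
  active <- arm %in% c("tralo_q2w", "tralo_q4w")
  lp[arm == "tralo_q2w"] <- lp[arm == "tralo_q2w"] + log(config$all_comers_rr)
  lp[arm == "tralo_q4w"] <- lp[arm == "tralo_q4w"] + log(config$q4w_rr)

  in_sub <- rep(FALSE, n)
  true_cutoffs <- list()
  for (ia in config$interaction %||% list()) {
    typ <- ia$type %||% "threshold"
    if (typ == "threshold") {
      pr <- lnorm_params(config$biomarker_marginals[[ia$biomarker]])
      cut <- qlnorm(ia$cutoff_quantile, pr[["mu"]], pr[["sigma"]])
      memb <- bm[, ia$biomarker] > cut
      lp[active & memb] <- lp[active & memb] + log(ia$rr)
      in_sub <- in_sub | memb
      true_cutoffs[[ia$biomarker]] <- c(cutoff = cut,
                                        quantile = ia$cutoff_quantile,
                                        rr = ia$rr)
    } else if (typ == "linear") {
      lp[active] <- lp[active] + ia$slope * z[active, ia$biomarker]
    } else stop("unknown interaction type: ", typ)
  }

  mu <- followup * exp(lp)
  y <- if (config$dispersion_k > 0) {
    rnbinom(n, mu = mu, size = 1 / config$dispersion_k)
  } else rpois(n, mu)

  ep <- config$endpoint_params
  baseline_fev1 <- rnorm(n, 65, 12)
  base_scores <- list(
    acq6 = rnorm(n, ep$acq6$baseline_mean, ep$acq6$baseline_sd),
    aqlq = rnorm(n, ep$aqlq$baseline_mean, ep$aqlq$baseline_sd),
    symptom_score = rnorm(n, ep$symptom_score$baseline_mean,
                          ep$symptom_score$baseline_sd))

  participants <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    arm = arm,
    feno_ppb = bm[, "feno_ppb"], periostin_ng_ml = bm[, "periostin_ng_ml"],
    eos_cells_ul = bm[, "eos_cells_ul"], dpp4_ng_ml = bm[, "dpp4_ng_ml"],
    ige_iu_ml = bm[, "ige_iu_ml"],
    region = region, age_years = age, prior_exacerbations = prior,
    exacerbation_count = y, followup_years = followup,
    baseline_acq6 = base_scores$acq6, baseline_aqlq = base_scores$aqlq,
    baseline_symptom = base_scores$symptom_score,
    baseline_fev1 = baseline_fev1,
    stringsAsFactors = FALSE)
  if (config$biomarker_missing_rate > 0) {
    for (b in bm_cols) {
      miss <- runif(n) < config$biomarker_missing_rate
      participants[[b]][miss] <- NA_real_
    }
  }

  # visit records: value = baseline (scores) + drift * w + effect * w +
  # subject effect + residual, with w = week/52; fev1 values are already
  # percentage change from baseline. Monotone missing after dropout.
  weeks <- config$visit_weeks
  vrows <- vector("list", length(ENDPOINTS))
  for (j in seq_along(ENDPOINTS)) {
    e <- ENDPOINTS[j]
    pe <- ep[[e]]
    fx <- config$endpoint_effects[[e]]
    subj <- rnorm(n, 0, pe$sd_subj)
    treat_eff <- ifelse(active, fx$overall + fx$subgroup_bonus * in_sub, 0)
    base_e <- switch(e, fev1_pct_change = rep(0, n), base_scores[[e]])
    vr <- do.call(rbind, lapply(weeks, function(wk) {
      w <- wk / 52
      val <- base_e + pe$drift * w + treat_eff * w + subj +
        rnorm(n, 0, pe$sd_eps)
      val[wk / 52 > followup + 1e-9] <- NA_real_
      data.frame(participant_id = participants$participant_id,
                 endpoint = e, week = wk, value = val,
                 stringsAsFactors = FALSE)
    }))
    vrows[[j]] <- vr
  }
  visits <- do.call(rbind, vrows)

  truth <- list(config = config, lp = lp, expected_rate = exp(lp),
                in_subgroup = in_sub, true_cutoffs = true_cutoffs,
                arm = arm, followup = followup, z_std = z)
  out <- trial_dataset(participants, visits,
                       metadata = list(analysis_set = "FAS", truth = truth),
                       validate = FALSE)
  attr(out, "truth") <- truth
  out
}

#' Library of named simulation scenarios
#'
#' The pre-specified scenario axes: no signal at all; prognostic biomarkers
#' without any treatment effect; an all-comers treatment effect without
#' predictive structure; a threshold-type FeNO interaction; a smooth
#' (linear-in-log) FeNO interaction; a correlated two-biomarker
#' (FeNO + periostin) interaction; and a biomarker-independent scenario
#' (treatment effect present, biomarkers pure noise) used for permutation
#' calibration. All share the calibrated baseline marginals.
#'
#' @param n_total participants per trial (default 1207).
#' @return named list of [scenario_config()] objects.
#' @export
scenario_library <- function(n_total = 1207) {
  prog <- c(feno_ppb = 0.25, periostin_ng_ml = 0.15, eos_cells_ul = 0.2)
  list(
    global_null = scenario_config("global_null", n_total = n_total),
    prognostic_only = scenario_config("prognostic_only", n_total = n_total,
                                      prognostic_coefs = prog),
    all_comers_only = scenario_config("all_comers_only", n_total = n_total,
                                      all_comers_rr = 0.8, q4w_rr = 0.85),
    feno_threshold = scenario_config(
      "feno_threshold", n_total = n_total,
      all_comers_rr = 1.0, q4w_rr = 1.0, prognostic_coefs = prog,
      interaction = list(biomarker = "feno_ppb", type = "threshold",
                         cutoff_quantile = 0.60, rr = 0.5),
      # a truly predictive biomarker implies consistent secondary-endpoint
      # benefit inside the responsive stratum (clinically meaningful sizes)
      endpoint_effects = list(
        fev1_pct_change = list(subgroup_bonus = 10),
        acq6 = list(subgroup_bonus = -0.4),
        aqlq = list(subgroup_bonus = 0.4),
        symptom_score = list(subgroup_bonus = -0.2))),
    feno_smooth = scenario_config(
      "feno_smooth", n_total = n_total,
      all_comers_rr = 0.9, prognostic_coefs = prog,
      interaction = list(biomarker = "feno_ppb", type = "linear",
                         slope = -0.3)),
    feno_periostin = scenario_config(
      "feno_periostin", n_total = n_total,
      all_comers_rr = 0.9, prognostic_coefs = prog,
      interaction = list(
        list(biomarker = "feno_ppb", type = "threshold",
             cutoff_quantile = 0.60, rr = 0.6),
        list(biomarker = "periostin_ng_ml", type = "threshold",
             cutoff_quantile = 0.60, rr = 0.75))),
    biomarker_independent = scenario_config(
      "biomarker_independent", n_total = n_total,
      all_comers_rr = 0.8, q4w_rr = 0.85)
  )
}
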