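# Shared fixtures, built in code and cached for the duration of the run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A small hand-built participants table covering all four arms, with some
# missing biomarker values and the two outlier eosinophil values.
tiny_participants <- function() {
  n <- 24
  set.seed(99)
  data.frame(
    participant_id = sprintf("T%02d", 1:n),
    arm = rep(c("tralo_q2w", "placebo_q2w", "tralo_q4w", "placebo_q4w"),
              each = 6),
    feno_ppb = c(20, 35, NA, 12, 80, 41, 18, 25, 33, 9, 55, 28,
                 22, 47, 16, NA, 39, 61, 14, 30, 26, 44, 19, 37),
    periostin_ng_ml = round(runif(n, 10, 60), 1),
    eos_cells_ul = c(7510, 4130, round(runif(n - 2, 50, 900))),
    dpp4_ng_ml = round(runif(n, 100, 500), 1),
    ige_iu_ml = round(exp(rnorm(n, 5, 1)), 1),
    region = rep(c("europe", "americas", "asia_pacific"), 8),
    age_years = c(15, 16, round(runif(n - 2, 19, 75))),
    prior_exacerbations = sample(1:4, n, replace = TRUE),
    exacerbation_count = rpois(n, 1),
    followup_years = round(runif(n, 0.5, 1), 3),
    baseline_acq6 = round(rnorm(n, 2.8, 0.6), 2),
    baseline_aqlq = round(rnorm(n, 4, 0.8), 2),
    baseline_symptom = round(rnorm(n, 1.5, 0.4), 2),
    baseline_fev1 = round(rnorm(n, 65, 10), 1),
    stringsAsFactors = FALSE)
}

tiny_trial <- function() trial_dataset(tiny_participants())

# Moderate prepared dataset with a planted FeNO threshold, reused across
# modules (seeded once).
feno_trial <- function() cached("feno_trial", {
  sc <- scenario_library()$feno_threshold
  prepare_analysis_set(
    simulate_trial(sc, seed = 424242),
    outlier_rules = list(list(biomarker = "eos_cells_ul", threshold = 4000)))
})

# Small null dataset (no treatment or biomarker effects).
null_trial <- function(n = 500, seed = 777) cached(
  paste0("null_trial_", n, "_", seed),
  prepare_analysis_set(simulate_trial(
    scenario_config("null", n_total = n), seed = seed)))

# Independent NB2 log-likelihood used by grid-search oracles.
nb2_loglik <- function(y, mu, k) {
  if (k <= 0) sum(dpois(y, mu, log = TRUE))
  else sum(dnbinom(y, mu = mu, size = 1 / k, log = TRUE))
}
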