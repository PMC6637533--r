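# Analysis-set preparation (placebo pooling, audited outlier exclusion,
# derived groupings) and descriptive summaries.

#' Prepare the analysis set
#'
#' Pools the two placebo arms into a single `placebo` level (the comparator
#' for every treatment contrast), removes participants matching explicit
#' outlier rules while logging each exclusion, and attaches derived
#' covariates: `age_group` (adolescent iff 12 <= age < 18), `periostin_group`
#' (high/low at a configurable cut, by default the in-sample median) and
#' `prior_cat` (prior-year exacerbations coded 1 / 2 / >=3).
#'
#' Outlier rules are explicit configuration, never automatic, so exclusions
#' stay auditable; each rule removes participants whose biomarker value
#' strictly exceeds the stated threshold. Retained participants' outcome and
#' exposure values are never altered.
#'
#' @param data a [trial_dataset()] with 4-level arms.
#' @param pool_placebo pool `placebo_q2w` and `placebo_q4w` (default TRUE).
#' @param outlier_rules list of `list(biomarker =, threshold =)`; values
#'   strictly above the threshold are excluded.
#' @param periostin_cut cut for `periostin_group`; default in-sample median.
#' @param prior_cap cap for the prior-exacerbation category (default 3, i.e.
#'   categories 1, 2, >=3).
#' @return a prepared `trial_dataset`; exclusions are recorded in
#'   `metadata$exclusions` (participant_id, rule, value).
#' @export
prepare_analysis_set <- function(data, pool_placebo = TRUE,
                                 outlier_rules = list(),
                                 periostin_cut = NULL, prior_cap = 3L) {
  stopifnot(inherits(data, "trial_dataset"))
  p <- data$participants
  excl <- data$metadata$exclusions

  for (rule in outlier_rules) {
    bm <- rule$biomarker
    if (!bm %in% names(p))
      stop("configuration error: outlier rule names unknown biomarker: ", bm,
           call. = FALSE)
    hit <- !is.na(p[[bm]]) & p[[bm]] > rule$threshold
    if (any(hit)) {
      excl <- rbind(excl, data.frame(
        participant_id = p$participant_id[hit],
        rule = sprintf("%s > %s", bm, format(rule$threshold)),
        value = p[[bm]][hit], stringsAsFactors = FALSE))
      p <- p[!hit, , drop = FALSE]
    }
  }

  if (pool_placebo) {
    arm <- as.character(p$arm)
    arm[arm %in% c("placebo_q2w", "placebo_q4w")] <- "placebo"
    p$arm <- factor(arm, levels = ARM_LEVELS_3)
  } else {
    p$arm <- factor(as.character(p$arm), levels = ARM_LEVELS_4)
  }

  p$age_group <- factor(ifelse(p$age_years >= 12 & p$age_years < 18,
                               "adolescent", "adult"),
                        levels = c("adult", "adolescent"))
  if (is.null(periostin_cut))
    periostin_cut <- median(p$periostin_ng_ml, na.rm = TRUE)
  p$periostin_group <- factor(ifelse(p$periostin_ng_ml > periostin_cut,
                                     "high", "low"),
                              levels = c("low", "high"))
  pc <- pmin(pmax(p$prior_exacerbations, 1L), prior_cap)
  labs <- c(as.character(seq_len(prior_cap - 1L)), paste0(">=", prior_cap))
  p$prior_cat <- factor(labs[pc], levels = labs)
  p$region <- factor(p$region)

  meta <- data$metadata
  meta$pooled <- pool_placebo
  meta$exclusions <- excl
  meta$periostin_cut <- periostin_cut
  v <- data$visits
  if (!is.null(v)) v <- v[v$participant_id %in% p$participant_id, , drop = FALSE]
  trial_dataset(p, v, meta, validate = FALSE)
}

#' Per-arm baseline biomarker summaries
#'
#' One row per biomarker and arm with the non-missing count, mean (SD) and
#' median (range), the standard descriptive layout for baseline biomarker
#' tables.
#'
#' @param data a prepared [trial_dataset()].
#' @return data.frame (biomarker, arm, n, mean, sd, median, min, max); `sd`
#'   is `NA` when fewer than two non-missing values are available.
#' @export
summarize_baseline <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  p <- data$participants
  arms <- levels(factor(p$arm))
  rows <- list()
  for (bm in unname(BIOMARKER_COLS)) {
    for (a in arms) {
      x <- p[[bm]][p$arm == a]
      x <- x[!is.na(x)]
      n <- length(x)
      rows[[length(rows) + 1L]] <- data.frame(
        biomarker = bm, arm = a, n = n,
        mean = if (n) mean(x) else NA_real_,
        sd = if (n >= 2) sd(x) else NA_real_,
        median = if (n) median(x) else NA_real_,
        min = if (n) min(x) else NA_real_,
        max = if (n) max(x) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Biomarker distributions by covariate level
#'
#' Describes how each biomarker varies over the levels of each categorical
#' covariate (median and quartiles per level), the screen used to spot
#' prognostic structure such as regional shifts in periostin or higher
#' biomarker levels in participants with more prior exacerbations.
#'
#' @param data a prepared [trial_dataset()].
#' @param covariates character vector of categorical covariate columns
#'   (e.g. `c("region", "age_group", "prior_cat")`).
#' @return long data.frame (biomarker, covariate, level, n, median, q1, q3).
#' @export
covariate_associations <- function(data,
                                   covariates = c("region", "age_group",
                                                  "prior_cat")) {
  stopifnot(inherits(data, "trial_dataset"))
  p <- data$participants
  rows <- list()
  for (cv in covariates) {
    if (!cv %in% names(p))
      stop("configuration error: unknown covariate: ", cv, call. = FALSE)
    if (is.numeric(p[[cv]]) && length(unique(p[[cv]])) > 12)
      stop("configuration error: continuous covariate '", cv,
           "' needs binning before use", call. = FALSE)
    for (bm in unname(BIOMARKER_COLS)) {
      for (lv in levels(factor(p[[cv]]))) {
        x <- p[[bm]][!is.na(p[[cv]]) & p[[cv]] == lv]
        x <- x[!is.na(x)]
        q <- if (length(x)) quantile(x, c(.25, .5, .75), type = 7) else rep(NA_real_, 3)
        rows[[length(rows) + 1L]] <- data.frame(
          biomarker = bm, covariate = cv, level = lv, n = length(x),
          median = q[[2]], q1 = q[[1]], q3 = q[[3]], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Rows for one treated arm vs pooled placebo, with a 2-level `treat` factor
# (placebo reference). The workhorse framing for every treatment contrast.
arm_frame <- function(data, arm = c("q2w", "q4w")) {
  arm <- match.arg(arm)
  p <- if (inherits(data, "trial_dataset")) data$participants else data
  if (!"placebo" %in% levels(factor(p$arm)))
    stop("analysis set must have pooled placebo; run prepare_analysis_set()",
         call. = FALSE)
  active <- if (arm == "q2w") "tralo_q2w" else "tralo_q4w"
  df <- p[p$arm %in% c("placebo", active), , drop = FALSE]
  df$treat <- factor(ifelse(df$arm == active, "tralo", "placebo"),
                     levels = c("placebo", "tralo"))
  df
}
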