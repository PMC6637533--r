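# Uncertainty machinery for the subgroup search: bootstrap distribution of
# the chosen cut-off per biomarker, and a permutation null for the
# best-subgroup effect (how large an apparent subgroup benefit the search
# finds when biomarkers carry no information).

#' Bootstrap distribution of SIDES cut-offs
#'
#' Draws `B` participant-level bootstrap resamples (with replacement,
#' stratified by arm so the allocation ratio is preserved), re-runs the
#' SIDES search on each, and records the chosen cut-off and direction per
#' biomarker. Cut-offs are binned on the fixed candidate-split grid of the
#' ORIGINAL data so histograms are comparable across draws; the main-run
#' cut-off is carried along for comparison. Draw k uses the k-th sub-seed
#' derived from `seed`, so it is identical whether run alone or in a batch.
#'
#' @param data prepared [trial_dataset()].
#' @param params [sides_params()].
#' @param B number of bootstrap draws (default 500).
#' @param seed master seed.
#' @param stratify stratify resampling by arm (default TRUE).
#' @param identity_resample use the original sample in every draw (testing
#'   aid: every draw must then reproduce the main run).
#' @param arm active arm.
#' @return object of class `bootstrap_cutoffs`: per biomarker the grid, bin
#'   counts by direction, times selected, the main-run cut-off; plus `B`
#'   and the per-draw records.
#' @export
bootstrap_cutoffs <- function(data, params = sides_params(), B = 500,
                              seed = 1, stratify = TRUE,
                              identity_resample = FALSE, arm = "q2w") {
  stopifnot(inherits(data, "trial_dataset"), B >= 1)
  main <- sides_run(data, params, arm)
  p <- data$participants
  grids <- lapply(params$search_covariates, function(cv)
    candidate_splits(arm_frame(data, arm)[[cv]], params))
  names(grids) <- params$search_covariates
  seeds <- derive_seeds(seed, B)
  draws <- vector("list", B)
  n_fail <- 0L
  for (k in seq_len(B)) {
    set.seed(seeds[k])
    idx <- if (identity_resample) seq_len(nrow(p)) else {
      if (stratify) {
        unlist(lapply(split(seq_len(nrow(p)), p$arm), function(ii)
          sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
      } else sample(nrow(p), replace = TRUE)
    }
    boot <- trial_dataset(p[idx, , drop = FALSE], NULL,
                          metadata = data$metadata, validate = FALSE)
    res <- tryCatch(sides_run(boot, params, arm), error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    sg <- res$subgroups[res$subgroups$depth == 1, , drop = FALSE]
    if (nrow(sg)) {
      sg <- sg[!duplicated(sg$biomarker), , drop = FALSE]
      draws[[k]] <- data.frame(draw = k, biomarker = sg$biomarker,
                               cutoff = sg$cutoff, direction = sg$direction,
                               stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, draws)
  per_bm <- lapply(params$search_covariates, function(cv) {
    g <- grids[[cv]]
    sel <- if (is.null(rec)) NULL else rec[rec$biomarker == cv, , drop = FALSE]
    bins_above <- integer(length(g)); bins_below <- integer(length(g))
    if (!is.null(sel) && nrow(sel)) {
      bin <- vapply(sel$cutoff, function(cc) which.min(abs(g - cc)), 0L)
      for (i in seq_len(nrow(sel))) {
        if (sel$direction[i] == "above")
          bins_above[bin[i]] <- bins_above[bin[i]] + 1L
        else bins_below[bin[i]] <- bins_below[bin[i]] + 1L
      }
    }
    msg <- main$subgroups[main$subgroups$biomarker == cv &
                            main$subgroups$depth == 1, , drop = FALSE]
    list(grid = g, bins_above = bins_above, bins_below = bins_below,
         n_selected = if (is.null(sel)) 0L else nrow(sel),
         main_cutoff = if (nrow(msg)) msg$cutoff[1] else NA_real_,
         main_direction = if (nrow(msg)) msg$direction[1] else NA_character_)
  })
  names(per_bm) <- params$search_covariates
  structure(list(biomarkers = per_bm, B = B, n_failed = n_fail,
                 draws = rec, main = main, params = params),
            class = "bootstrap_cutoffs")
}

#' @export
print.bootstrap_cutoffs <- function(x, ...) {
  cat("<bootstrap_cutoffs> B =", x$B,
      if (x$n_failed) paste0("(", x$n_failed, " failed draws)"), "\n")
  for (cv in names(x$biomarkers)) {
    b <- x$biomarkers[[cv]]
    cat(sprintf("  %-16s selected %d/%d; main cut-off %s\n", cv,
                b$n_selected, x$B,
                if (is.na(b$main_cutoff)) "none" else
                  format(b$main_cutoff, digits = 4)))
  }
  invisible(x)
}

#' Permutation null for the best-subgroup effect
#'
#' Each permutation jointly permutes the five-biomarker block (plus any
#' biomarker-derived grouping) across participants, preserving the panel's
#' internal correlation while severing every biomarker-outcome and
#' biomarker-treatment link; the SIDES search is re-run on the permuted
#' data and the largest AAER reduction among the subgroups it returns is
#' recorded (when no subgroup passes the constraints, the all-comers
#' reduction is recorded and counted separately). The observed best effect
#' is located within this null distribution.
#'
#' @param data prepared [trial_dataset()].
#' @param params [sides_params()].
#' @param P number of permutations (default 500).
#' @param seed master seed.
#' @param joint permute the biomarker block as a unit (default) or each
#'   biomarker independently.
#' @param arm active arm.
#' @return object of class `permutation_null`: `null_reductions` (length
#'   P; failed runs NA), `observed` best reduction, `observed_percentile`,
#'   `null_median`, counts of fallback and failed draws.
#' @export
permutation_null <- function(data, params = sides_params(), P = 500,
                             seed = 1, joint = TRUE, arm = "q2w") {
  if (P < 1) stop("configuration error: P must be >= 1", call. = FALSE)
  stopifnot(inherits(data, "trial_dataset"))
  bm_cols <- intersect(c(unname(BIOMARKER_COLS), "periostin_group"),
                       names(data$participants))
  best_reduction <- function(d) {
    res <- sides_run(d, params, arm)
    sg <- res$subgroups
    if (nrow(sg)) return(list(value = max(sg$reduction_pct), fallback = FALSE))
    ac <- treat_only_effect(arm_frame(d, arm))
    list(value = if (ac$ok) ac$reduction_pct else NA_real_, fallback = TRUE)
  }
  obs <- best_reduction(data)
  seeds <- derive_seeds(seed, P)
  null_red <- rep(NA_real_, P)
  n_fallback <- 0L; n_fail <- 0L
  p <- data$participants
  for (k in seq_len(P)) {
    set.seed(seeds[k])
    pp <- p
    if (joint) {
      idx <- sample(nrow(p))
      pp[bm_cols] <- p[idx, bm_cols]
    } else {
      for (cl in bm_cols) pp[[cl]] <- p[[cl]][sample(nrow(p))]
    }
    pd <- trial_dataset(pp, NULL, metadata = data$metadata, validate = FALSE)
    r <- tryCatch(best_reduction(pd), error = function(e) NULL)
    if (is.null(r) || is.na(r$value)) { n_fail <- n_fail + 1L; next }
    if (r$fallback) n_fallback <- n_fallback + 1L
    null_red[k] <- r$value
  }
  ok <- !is.na(null_red)
  structure(list(null_reductions = null_red, P = P,
                 observed = obs$value, observed_fallback = obs$fallback,
                 observed_percentile = mean(null_red[ok] <= obs$value),
                 null_median = median(null_red[ok]),
                 n_fallback = n_fallback, n_failed = n_fail,
                 params = params), class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> P = %d (%d failed, %d fallback draws)\n  observed best reduction %.1f%% at percentile %.2f of the null (null median %.1f%%)\n",
    x$P, x$n_failed, x$n_fallback, x$observed, x$observed_percentile,
    x$null_median))
  invisible(x)
}
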