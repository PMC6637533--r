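# Count-outcome SIDES: recursive subgroup search driven by child-wise
# treatment-effect z statistics from treatment-only NB fits with exposure
# offset, with size/prevalence constraints, continuation and selection
# filters, covariate-adjusted subgroup evaluation, and sensitivity re-runs.

#' SIDES search parameters
#'
#' @param L maximum number of covariates defining a subgroup (search depth).
#' @param M maximum number of best candidate covariates carried to the next
#'   step.
#' @param N_min minimum allowed subgroup size.
#' @param min_prevalence minimum prevalence of the selected child in the
#'   study population (computed over participants non-missing for that
#'   covariate); default 0.30.
#' @param n_splits candidate cut-offs per covariate, placed at the
#'   quantiles j/(n_splits+1) (default 50 evenly distributed splits).
#' @param criterion splitting criterion: 1 maximises the differential
#'   effect between the two children; 2 maximises the treatment effect in
#'   the better child; 3 is criterion 1 plus a one-sided benefit
#'   requirement on the better child.
#' @param gamma continuation multiplier in (0, 1]: a child is pursued only
#'   if its treatment-effect p-value is at most `gamma` times its parent's.
#' @param selection_threshold minimum clinically relevant AAER reduction
#'   (percent) for a subgroup to be reported.
#' @param search_covariates covariate columns to search (default the five
#'   biomarkers); numeric columns only.
#' @param benefit_alpha one-sided benefit level used by criterion 3.
#' @return object of class `sides_params`.
#' @export
sides_params <- function(L = 1, M = 5, N_min = 60, min_prevalence = 0.30,
                         n_splits = 50, criterion = 1, gamma = 1.0,
                         selection_threshold = 0,
                         search_covariates = unname(BIOMARKER_COLS),
                         benefit_alpha = 0.05) {
  stopifnot(L >= 1, M >= 1, N_min >= 1, n_splits >= 1,
            criterion %in% 1:3, gamma > 0, gamma <= 1)
  structure(list(L = L, M = M, N_min = N_min,
                 min_prevalence = min_prevalence, n_splits = n_splits,
                 criterion = criterion, gamma = gamma,
                 selection_threshold = selection_threshold,
                 search_covariates = search_covariates,
                 benefit_alpha = benefit_alpha), class = "sides_params")
}

#' Candidate cut-offs for one covariate
#'
#' Cut-offs at the quantiles j/(n_splits+1), j = 1..n_splits, of the
#' non-missing values, deduplicated; cut-offs are admissible only when both
#' children reach `N_min` (a minimum-node-size constraint: a child smaller
#' than `N_min` cannot support a stable treatment-effect z, and extreme
#' splits would otherwise win on noise). A constant covariate yields no
#' cut-offs.
#'
#' @param values numeric covariate vector (may contain NA).
#' @param params [sides_params()].
#' @return numeric vector of cut-offs (possibly empty).
#' @export
candidate_splits <- function(values, params) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2) return(numeric(0))
  ns <- params$n_splits
  cuts <- sort(unique(unname(quantile(v, seq_len(ns) / (ns + 1), type = 7))))
  n_above <- vapply(cuts, function(cc) sum(v > cc), integer(1))
  # dedupe cut-offs that induce the same partition (ties interpolate the
  # quantile grid into distinct values with identical splits)
  keep <- !duplicated(n_above) &
    n_above >= params$N_min & (length(v) - n_above) >= params$N_min
  cuts[keep]
}

# Criterion p-value from the two child z statistics.
criterion_p <- function(z1, z2, criterion, benefit_alpha = 0.05) {
  p1 <- 2 * pnorm(-abs(z1 - z2) / sqrt(2))
  if (criterion == 1) return(p1)
  p2 <- min(1, 2 * min(1 - pnorm(z1), 1 - pnorm(z2)))
  if (criterion == 2) return(p2)
  # criterion 3: differential-effect p, admissible only when the better
  # child also shows one-sided benefit
  zb <- max(z1, z2)
  if (1 - pnorm(zb) <= benefit_alpha) p1 else 1
}

#' Score one candidate split
#'
#' Splits the analysis rows at `cutoff` into an "above" and an
#' "at-or-below" child, fits the treatment-only NB model (log follow-up
#' offset) within each child, converts the treatment coefficients to
#' benefit z statistics (positive z = fewer exacerbations on treatment) and
#' computes the splitting-criterion p-value: criterion 1,
#' `2 * (1 - Phi(|z1 - z2| / sqrt(2)))`; criterion 2,
#' `2 * min(1 - Phi(z1), 1 - Phi(z2))`; criterion 3 as criterion 1 with a
#' one-sided benefit requirement on the better child.
#'
#' @param data prepared [trial_dataset()] (or an `arm_frame`).
#' @param biomarker covariate column to split on.
#' @param cutoff split point (above vs at-or-below).
#' @param criterion 1, 2 or 3.
#' @param arm active arm if `data` is a trial dataset.
#' @param benefit_alpha criterion-3 benefit level.
#' @return list (cutoff, z_above, z_below, criterion_p, better_child, N_s,
#'   n_above, n_below, reduction_above, reduction_below, ok, reason).
#' @export
split_score <- function(data, biomarker, cutoff, criterion = 1, arm = "q2w",
                        benefit_alpha = 0.05) {
  df <- if (inherits(data, "trial_dataset")) arm_frame(data, arm) else data
  df <- df[!is.na(df[[biomarker]]), , drop = FALSE]
  split_score_df(df, biomarker, cutoff, criterion, benefit_alpha)
}

split_score_df <- function(df, biomarker, cutoff, criterion, benefit_alpha) {
  above <- df[[biomarker]] > cutoff
  bad <- function(reason) list(cutoff = cutoff, z_above = NA_real_,
                               z_below = NA_real_, criterion_p = NA_real_,
                               better_child = NA_character_, N_s = NA_integer_,
                               n_above = sum(above), n_below = sum(!above),
                               reduction_above = NA_real_,
                               reduction_below = NA_real_,
                               p_benefit_above = NA_real_,
                               p_benefit_below = NA_real_,
                               ok = FALSE, reason = reason)
  if (!any(above) || all(above)) return(bad("empty child"))
  for (side in c(TRUE, FALSE)) {
    tr <- df$treat[above == side]
    if (length(unique(tr)) < 2) return(bad("child lacks an arm"))
  }
  ea <- treat_only_effect(df[above, , drop = FALSE])
  eb <- treat_only_effect(df[!above, , drop = FALSE])
  if (!ea$ok || !eb$ok) return(bad("child fit non-convergent"))
  za <- ea$z; zb <- eb$z
  p <- criterion_p(za, zb, criterion, benefit_alpha)
  better <- if (za >= zb) "above" else "at_or_below"
  list(cutoff = cutoff, z_above = za, z_below = zb, criterion_p = p,
       better_child = better,
       N_s = if (better == "above") sum(above) else sum(!above),
       n_above = sum(above), n_below = sum(!above),
       reduction_above = ea$reduction_pct, reduction_below = eb$reduction_pct,
       p_benefit_above = 1 - pnorm(za), p_benefit_below = 1 - pnorm(zb),
       ok = TRUE, reason = "scored")
}

#' Run the SIDES subgroup search
#'
#' For each search covariate, scores every admissible candidate cut-off and
#' keeps the best split by criterion p-value (ties: smaller cut-off first).
#' The better child of each best split becomes a candidate subgroup if its
#' size is at least `N_min`, its prevalence in the study population at
#' least `min_prevalence`, and (beyond the root) its treatment-effect
#' p-value is at most `gamma` times its parent's (continuation). The top-M
#' candidates recurse until depth `L`. Selection finally keeps subgroups
#' whose in-search AAER reduction reaches `selection_threshold`. The full
#' trace records every cut-off evaluated with its scores or rejection
#' reason; the search is deterministic given data and parameters.
#'
#' @param data prepared [trial_dataset()].
#' @param params [sides_params()].
#' @param arm active arm vs pooled placebo (Q4W runs are supportive and
#'   never combined with Q2W in one search).
#' @return object of class `sides_result`: `subgroups` (one row per
#'   candidate, ordered by criterion p), `trace`, `params`, `arm`.
#' @export
sides_run <- function(data, params = sides_params(), arm = "q2w") {
  df0 <- arm_frame(data, arm)
  # study-population denominators for the prevalence constraint
  denom <- vapply(params$search_covariates,
                  function(cv) sum(!is.na(df0[[cv]])), integer(1))
  trace <- list()
  found <- list()

  search_node <- function(df, depth, parent_conditions, parent_label,
                          parent_p) {
    cand <- list()
    for (cv in params$search_covariates) {
      if (any(parent_conditions == cv)) next  # each covariate used once
      v <- df[[cv]]
      cuts <- candidate_splits(v, params)
      if (!length(cuts)) {
        trace[[length(trace) + 1L]] <<- data.frame(
          node = parent_label, biomarker = cv, cutoff = NA_real_,
          z_above = NA_real_, z_below = NA_real_, criterion_p = NA_real_,
          N_s = NA_integer_, status = "no admissible cut-offs",
          stringsAsFactors = FALSE)
        next
      }
      scores <- lapply(cuts, function(cc)
        split_score_df(df[!is.na(v), , drop = FALSE], cv, cc,
                       params$criterion, params$benefit_alpha))
      for (s in scores) {
        trace[[length(trace) + 1L]] <<- data.frame(
          node = parent_label, biomarker = cv, cutoff = s$cutoff,
          z_above = s$z_above, z_below = s$z_below,
          criterion_p = s$criterion_p, N_s = s$N_s %||% NA_integer_,
          status = s$reason, stringsAsFactors = FALSE)
      }
      ok <- Filter(function(s) s$ok && is.finite(s$criterion_p), scores)
      if (!length(ok)) next
      ps <- vapply(ok, `[[`, 0, "criterion_p")
      ccs <- vapply(ok, `[[`, 0, "cutoff")
      best <- ok[[order(ps, ccs)[1]]]
      # candidate = better child of the best split
      dir <- best$better_child
      memb <- if (dir == "above") df[[cv]] > best$cutoff else
        !(df[[cv]] > best$cutoff)
      memb[is.na(df[[cv]])] <- FALSE
      prev <- best$N_s / denom[[cv]]
      child_p <- if (dir == "above") best$p_benefit_above else
        best$p_benefit_below
      reject <- NULL
      if (best$N_s < params$N_min) reject <- "N_s below N_min"
      else if (prev < params$min_prevalence) reject <- "prevalence below floor"
      else if (!is.null(parent_p) && child_p > params$gamma * parent_p)
        reject <- "continuation failed"
      trace[[length(trace) + 1L]] <<- data.frame(
        node = parent_label, biomarker = cv, cutoff = best$cutoff,
        z_above = best$z_above, z_below = best$z_below,
        criterion_p = best$criterion_p, N_s = best$N_s,
        status = if (is.null(reject)) "best split: candidate accepted"
                 else paste0("best split rejected: ", reject),
        stringsAsFactors = FALSE)
      if (is.null(reject)) {
        cand[[length(cand) + 1L]] <- list(
          biomarker = cv, cutoff = best$cutoff, direction = dir,
          criterion_p = best$criterion_p, N_s = best$N_s, prevalence = prev,
          z = if (dir == "above") best$z_above else best$z_below,
          reduction_pct = if (dir == "above") best$reduction_above
                          else best$reduction_below,
          p_benefit = child_p, memb = memb, depth = depth)
      }
    }
    if (!length(cand)) return(invisible(NULL))
    ord <- order(vapply(cand, `[[`, 0, "criterion_p"),
                 vapply(cand, `[[`, 0, "cutoff"),
                 vapply(cand, `[[`, "", "biomarker"))
    cand <- cand[ord]
    for (ci in cand) {
      lab <- paste0(if (nzchar(parent_label)) paste0(parent_label, " & "),
                    format(subgroup(ci$biomarker, ci$cutoff,
                                    direction = ci$direction)))
      found[[length(found) + 1L]] <<- c(
        ci[c("biomarker", "cutoff", "direction", "criterion_p", "N_s",
             "prevalence", "z", "reduction_pct", "p_benefit", "depth")],
        list(label = lab, conditions = c(parent_conditions, ci$biomarker)))
    }
    if (depth < params$L) {
      for (ci in head(cand, params$M)) {
        child_df <- df[ci$memb, , drop = FALSE]
        lab <- paste0(if (nzchar(parent_label)) paste0(parent_label, " & "),
                      format(subgroup(ci$biomarker, ci$cutoff,
                                      direction = ci$direction)))
        search_node(child_df, depth + 1L,
                    c(parent_conditions, ci$biomarker), lab, ci$p_benefit)
      }
    }
    invisible(NULL)
  }

  # continuation is inactive at the root: depth-1 children are not filtered
  # against the whole-population treatment effect
  search_node(df0, 1L, character(0), "", NULL)

  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(node = character(), biomarker = character(),
               cutoff = numeric(), z_above = numeric(), z_below = numeric(),
               criterion_p = numeric(), N_s = integer(), status = character(),
               stringsAsFactors = FALSE)

  sgdf <- if (length(found)) {
    do.call(rbind, lapply(found, function(f) data.frame(
      biomarker = f$biomarker, direction = f$direction, cutoff = f$cutoff,
      label = f$label, criterion_p = f$criterion_p, N_s = f$N_s,
      prevalence = f$prevalence, z = f$z, reduction_pct = f$reduction_pct,
      p_benefit = f$p_benefit, depth = f$depth, stringsAsFactors = FALSE)))
  } else data.frame(biomarker = character(), direction = character(),
                    cutoff = numeric(), label = character(),
                    criterion_p = numeric(), N_s = integer(),
                    prevalence = numeric(), z = numeric(),
                    reduction_pct = numeric(), p_benefit = numeric(),
                    depth = integer(), stringsAsFactors = FALSE)
  # selection filter
  sgdf <- sgdf[is.na(sgdf$reduction_pct) |
                 sgdf$reduction_pct >= params$selection_threshold, ,
               drop = FALSE]
  sgdf <- sgdf[order(sgdf$criterion_p, sgdf$cutoff, sgdf$biomarker), ,
               drop = FALSE]
  rownames(sgdf) <- NULL
  structure(list(subgroups = sgdf, trace = trace_df, params = params,
                 arm = arm), class = "sides_result")
}

#' @export
print.sides_result <- function(x, ...) {
  cat("<sides_result> arm:", x$arm, "-", nrow(x$subgroups),
      "candidate subgroup(s)\n")
  if (nrow(x$subgroups))
    print(x$subgroups[, c("label", "criterion_p", "N_s", "prevalence",
                          "reduction_pct")], digits = 3)
  invisible(x)
}

#' Best subgroup of a SIDES result
#' @param x `sides_result`.
#' @param biomarker optionally restrict to one covariate.
#' @return a [subgroup()] or NULL when nothing was selected.
#' @export
best_subgroup <- function(x, biomarker = NULL) {
  sg <- x$subgroups
  if (!is.null(biomarker)) sg <- sg[sg$biomarker == biomarker, , drop = FALSE]
  sg <- sg[sg$depth == 1, , drop = FALSE]
  if (!nrow(sg)) return(NULL)
  top <- sg[1, ]
  subgroup(top$biomarker, top$cutoff, direction = top$direction)
}

#' Covariate-adjusted evaluation of a subgroup and its complement
#'
#' Fits the covariate-adjusted NB model (treatment, region, age,
#' prior-exacerbation category, log follow-up offset) separately inside the
#' subgroup and inside the complementary subgroup (participants not in the
#' subgroup of interest), matching the adjusted model used for the primary
#' subgroup analysis.
#'
#' @param data prepared [trial_dataset()].
#' @param sg a [subgroup()].
#' @param arm active arm vs pooled placebo.
#' @param covariates adjustment covariates; `character(0)` for the
#'   unadjusted (treatment-only) model.
#' @param dispersion NULL (estimate k per side) or a fixed k (0 = Poisson).
#' @return list with `subgroup` and `complementary` effect estimates.
#' @export
evaluate_subgroup <- function(data, sg, arm = "q2w",
                              covariates = c("region", "age_years",
                                             "prior_cat"),
                              dispersion = NULL) {
  df <- arm_frame(data, arm)
  memb <- in_subgroup(df, sg)
  keep <- !is.na(memb)
  df <- df[keep, , drop = FALSE]
  memb <- memb[keep]
  f <- as.formula(paste("exacerbation_count ~ treat",
                        if (length(covariates))
                          paste("+", paste(covariates, collapse = " + "))
                        else ""))
  fit_side <- function(rows, lbl) {
    sub <- df[rows, , drop = FALSE]
    nt <- sum(sub$treat == "tralo"); nc <- sum(sub$treat == "placebo")
    if (nt == 0 || nc == 0) return(non_estimable_effect(lbl, nt, nc))
    tryCatch(effect_from_fit(fit_nb(sub, f, dispersion = dispersion),
                             "treattralo",
                             n_treated = nt, n_control = nc, label = lbl),
             error = function(e) non_estimable_effect(lbl, nt, nc))
  }
  comp_lbl <- if (nrow(sg$conditions) == 1)
    format(complement_subgroup(sg)) else paste("not", format(sg))
  list(subgroup = fit_side(memb, format(sg)),
       complementary = fit_side(!memb, comp_lbl))
}

#' Sensitivity re-runs of the SIDES search
#'
#' Re-runs the search under parameter variants (e.g. different `N_min`,
#' criterion, or `min_prevalence = 0` to drop the size restriction) and
#' tabulates the selected biomarker and cut-off per variant.
#'
#' @param data prepared [trial_dataset()].
#' @param base base [sides_params()].
#' @param variants named list of parameter-override lists.
#' @param arm active arm.
#' @return data.frame (variant, biomarker, direction, cutoff,
#'   reduction_pct, criterion_p); one row per run's top subgroup, NA row
#'   when a run selected nothing.
#' @export
sensitivity_reruns <- function(data, base = sides_params(), variants = list(),
                               arm = "q2w") {
  runs <- c(list(base = list()), variants)
  rows <- lapply(names(runs), function(nm) {
    pars <- base
    for (k in names(runs[[nm]])) pars[[k]] <- runs[[nm]][[k]]
    class(pars) <- "sides_params"
    res <- sides_run(data, pars, arm)
    sg <- res$subgroups
    if (!nrow(sg)) return(data.frame(
      variant = nm, biomarker = NA_character_, direction = NA_character_,
      cutoff = NA_real_, reduction_pct = NA_real_, criterion_p = NA_real_,
      stringsAsFactors = FALSE))
    data.frame(variant = nm, biomarker = sg$biomarker[1],
               direction = sg$direction[1], cutoff = sg$cutoff[1],
               reduction_pct = sg$reduction_pct[1],
               criterion_p = sg$criterion_p[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
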