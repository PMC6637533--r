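# Decision layer: cut-off grid scan on the exacerbation endpoint,
# repeated-measures models for the longitudinal secondary endpoints, and
# the comparative decision summary over candidate biomarkers.

#' Treatment effect at a grid of biomarker cut-offs
#'
#' For each cut-off, fits one NB model with treatment, region, age group,
#' periostin group, prior-exacerbation category and the
#' treatment-by-(at-or-above/below) interaction, and extracts the treatment
#' effect on each side of the cut. Sides follow the >= / < convention.
#' p-values are nominal; no multiplicity adjustment is applied.
#'
#' @param data prepared [trial_dataset()].
#' @param biomarker biomarker column.
#' @param grid numeric vector of cut-offs.
#' @param arm active arm vs pooled placebo.
#' @param covariates adjustment covariates; `character(0)` for the
#'   unadjusted model.
#' @param dispersion NULL (estimate k per model), 0 (Poisson) or fixed k.
#' @return data.frame scan table: one row per cut-off and side
#'   (cutoff, side, n_treated, n_control, rate_ratio, ci_low, ci_high,
#'   p_value, reduction_pct, estimable).
#' @export
cutoff_scan <- function(data, biomarker, grid, arm = "q2w",
                        covariates = c("region", "age_group",
                                       "periostin_group", "prior_cat"),
                        dispersion = NULL) {
  if (!length(grid)) stop("grid must be non-empty", call. = FALSE)
  df <- arm_frame(data, arm)
  df <- df[!is.na(df[[biomarker]]), , drop = FALSE]
  covs <- if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
          else ""
  rows <- list()
  for (cc in grid) {
    ge <- df[[biomarker]] >= cc
    for (side in c("at_or_above", "below")) {
      memb <- if (side == "at_or_above") ge else !ge
      nt <- sum(memb & df$treat == "tralo")
      nc <- sum(memb & df$treat == "placebo")
      lbl <- sprintf("%s %s %s", biomarker,
                     if (side == "at_or_above") ">=" else "<", format(cc))
      est <- if (nt == 0 || nc == 0) {
        non_estimable_effect(lbl, nt, nc)
      } else if (all(ge) || all(!ge)) {
        f0 <- as.formula(paste("exacerbation_count ~ treat", covs))
        tryCatch(effect_from_fit(fit_nb(df, f0, dispersion = dispersion),
                                 "treattralo",
                                 n_treated = nt, n_control = nc, label = lbl),
                 error = function(e) non_estimable_effect(lbl, nt, nc))
      } else {
        df$.side <- factor(ifelse(ge, "at_or_above", "below"),
                           levels = c("below", "at_or_above"))
        f <- as.formula(paste("exacerbation_count ~ treat * .side", covs))
        tryCatch({
          fit <- fit_nb(df, f, dispersion = dispersion)
          w <- c(treattralo = 1)
          if (side == "at_or_above") w["treattralo:.sideat_or_above"] <- 1
          effect_from_fit(fit, contrast = w, n_treated = nt, n_control = nc,
                          label = lbl)
        }, error = function(e) non_estimable_effect(lbl, nt, nc))
      }
      d <- as.data.frame(est)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(cutoff = cc, side = side, stringsAsFactors = FALSE),
        d[, c("n_treated", "n_control", "rate_ratio", "ci_low", "ci_high",
              "p_value", "reduction_pct", "estimable")])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeated-measures model for a secondary endpoint by subgroup side
#'
#' Fits the longitudinal model for one endpoint: change from baseline (for
#' score endpoints; FEV1 visit values are already percentage change) on
#' treatment, region, age group, periostin group, prior-exacerbation
#' category, visit, treatment-by-visit and treatment-by-biomarker-group
#' terms (plus baseline score for score endpoints), with an unstructured
#' visit covariance for FEV1 percentage change and compound symmetry for
#' scores, by generalised least squares (ML). The reported effect is the
#' treatment difference at Week 52 inside and outside the subgroup. A
#' non-convergent unstructured fit falls back to compound symmetry with a
#' logged downgrade.
#'
#' @param data prepared [trial_dataset()] with visit records.
#' @param endpoint one of `fev1_pct_change`, `acq6`, `aqlq`,
#'   `symptom_score`.
#' @param sg a [subgroup()] defining the biomarker group.
#' @param arm active arm vs pooled placebo.
#' @param covariance `"unstructured"` or `"compound_symmetric"`; default by
#'   endpoint as above.
#' @param week contrast visit (default 52).
#' @param covariates baseline adjustment covariates (beyond the baseline
#'   score term); `character(0)` drops them.
#' @return list of class `mmrm_result` with `inside` and `outside`
#'   components (endpoint, side, n_treated, n_control, effect, ci_low,
#'   ci_high, p_value, covariance_structure, downgraded).
#' @export
mmrm_endpoint <- function(data, endpoint, sg, arm = "q2w",
                          covariance = NULL, week = 52,
                          covariates = c("region", "age_group",
                                         "periostin_group", "prior_cat")) {
  stopifnot(inherits(data, "trial_dataset"))
  if (is.null(data$visits) || !endpoint %in% data$visits$endpoint)
    stop("no visit records for endpoint: ", endpoint, call. = FALSE)
  if (is.null(covariance))
    covariance <- if (endpoint == "fev1_pct_change") "unstructured"
                  else "compound_symmetric"
  covariance <- match.arg(covariance, c("unstructured", "compound_symmetric"))

  df <- arm_frame(data, arm)
  memb <- in_subgroup(df, sg)
  df <- df[!is.na(memb), , drop = FALSE]
  df$bm_group <- factor(ifelse(memb[!is.na(memb)], "inside", "outside"),
                        levels = c("outside", "inside"))
  v <- data$visits[data$visits$endpoint == endpoint, , drop = FALSE]
  m <- merge(v, df, by = "participant_id")
  base_col <- switch(endpoint, acq6 = "baseline_acq6",
                     aqlq = "baseline_aqlq",
                     symptom_score = "baseline_symptom", NULL)
  m$change <- if (is.null(base_col)) m$value else m$value - m[[base_col]]
  m <- m[!is.na(m$change), , drop = FALSE]
  if (!is.null(base_col)) m <- m[!is.na(m[[base_col]]), , drop = FALSE]
  weeks <- sort(unique(m$week))
  m$visit_f <- factor(m$week, levels = weeks)
  m$visit_idx <- match(m$week, weeks)
  m <- m[order(m$participant_id, m$visit_idx), , drop = FALSE]

  one_sided <- length(unique(m$bm_group)) < 2  # whole-population subgroup
  bm_terms <- if (one_sided) "" else " + bm_group + treat:bm_group"
  fixef <- paste0("change ~ ",
                  if (!is.null(base_col)) paste(base_col, "+ ") else "",
                  "treat",
                  if (length(covariates))
                    paste(" +", paste(covariates, collapse = " + ")) else "",
                  " + visit_f + treat:visit_f", bm_terms)
  f <- as.formula(fixef)
  downgraded <- FALSE
  fit_gls <- function(struct) {
    corr <- if (struct == "unstructured")
      nlme::corSymm(form = ~ visit_idx | participant_id)
    else nlme::corCompSymm(form = ~ 1 | participant_id)
    wts <- if (struct == "unstructured")
      nlme::varIdent(form = ~ 1 | visit_f) else NULL
    nlme::gls(f, data = m, correlation = corr, weights = wts,
              method = "ML", na.action = na.omit,
              control = nlme::glsControl(maxIter = 100, msMaxIter = 100,
                                         returnObject = FALSE))
  }
  fit <- tryCatch(fit_gls(covariance), error = function(e) NULL)
  if (is.null(fit) && covariance == "unstructured") {
    downgraded <- TRUE
    covariance <- "compound_symmetric"
    fit <- fit_gls(covariance)
  }
  if (is.null(fit)) stop("repeated-measures fit failed for ", endpoint,
                         call. = FALSE)

  cf <- coef(fit)
  V <- vcov(fit)
  wk_term <- paste0("treattralo:visit_f", week)
  side_effect <- function(side) {
    ids <- unique(m$participant_id[m$bm_group ==
                                     if (side == "inside") "inside" else "outside"])
    sub <- df[df$participant_id %in% ids, , drop = FALSE]
    if (!length(ids)) {
      return(list(endpoint = endpoint, side = side, n_treated = 0L,
                  n_control = 0L, effect = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, p_value = NA_real_,
                  covariance_structure = covariance,
                  downgraded = downgraded))
    }
    w <- setNames(numeric(length(cf)), names(cf))
    w["treattralo"] <- 1
    if (wk_term %in% names(cf)) w[wk_term] <- 1
    if (side == "inside" && "treattralo:bm_groupinside" %in% names(cf))
      w["treattralo:bm_groupinside"] <- 1
    b <- sum(w * cf)
    se <- sqrt(drop(t(w) %*% V %*% w))
    list(endpoint = endpoint,
         side = if (side == "inside") format(sg) else
           paste("not", format(sg)),
         n_treated = sum(sub$treat == "tralo"),
         n_control = sum(sub$treat == "placebo"),
         effect = b, ci_low = b - 1.96 * se, ci_high = b + 1.96 * se,
         p_value = 2 * pnorm(-abs(b / se)),
         covariance_structure = covariance, downgraded = downgraded)
  }
  structure(list(inside = side_effect("inside"),
                 outside = side_effect("outside"),
                 endpoint = endpoint, week = week, fit = fit),
            class = "mmrm_result")
}

#' @export
print.mmrm_result <- function(x, ...) {
  for (s in list(x$inside, x$outside)) {
    cat(sprintf("%s | %s: effect %.2f (%.2f, %.2f), p = %.3g [%s]\n",
                s$endpoint, s$side, s$effect, s$ci_low, s$ci_high,
                s$p_value, s$covariance_structure))
  }
  invisible(x)
}

#' Comparative decision summary over candidate biomarker subgroups
#'
#' Assembles, per candidate subgroup, the prevalence (n/N), the adjusted
#' AAER reduction with CI, the interaction-test p-value with a 0.10
#' nominal-significance flag, the count of secondary endpoints nominally
#' improved (p < 0.05 inside the subgroup, in the beneficial direction),
#' and a Q4W-consistency flag, then ranks candidates: more enhanced
#' secondary endpoints first, then a nominally significant interaction,
#' then larger AAER reduction. A pure function of its inputs.
#'
#' @param candidates named list; each element a list with fields
#'   `subgroup` ([subgroup()]), `n_in`, `N`, `effect`
#'   ([effect_from_fit()] result), `interaction_p`, `secondary` (list of
#'   [mmrm_endpoint()] results), `q4w_effect` (optional effect estimate).
#' @param benefit_direction named vector (+1 improvement is positive, -1
#'   improvement is negative) per endpoint.
#' @return data.frame, one row per candidate, ordered by rank; missing
#'   inputs yield `NA` cells flagged in `incomplete`.
#' @export
decision_summary <- function(candidates,
                             benefit_direction = c(fev1_pct_change = 1,
                                                   acq6 = -1, aqlq = 1,
                                                   symptom_score = -1)) {
  rows <- lapply(names(candidates), function(nm) {
    cd <- candidates[[nm]]
    incomplete <- character(0)
    prev <- if (!is.null(cd$n_in) && !is.null(cd$N)) 100 * cd$n_in / cd$N
            else { incomplete <- c(incomplete, "prevalence"); NA_real_ }
    eff <- cd$effect
    red <- if (!is.null(eff) && isTRUE(eff$estimable)) eff$reduction_pct
           else { incomplete <- c(incomplete, "effect"); NA_real_ }
    ip <- cd$interaction_p %||% { incomplete <- c(incomplete,
                                                  "interaction_p"); NA_real_ }
    n_sec <- NA_integer_
    if (!is.null(cd$secondary)) {
      n_sec <- sum(vapply(cd$secondary, function(mm) {
        s <- mm$inside
        dirn <- benefit_direction[[s$endpoint]] %||% 1
        isTRUE(s$p_value < 0.05 && sign(s$effect) == dirn)
      }, logical(1)))
    } else incomplete <- c(incomplete, "secondary")
    q4w <- NA
    if (!is.null(cd$q4w_effect) && isTRUE(cd$q4w_effect$estimable))
      q4w <- cd$q4w_effect$reduction_pct > 0
    data.frame(
      candidate = nm, label = format(cd$subgroup),
      prevalence_pct = prev,
      prevalence = sprintf("%.1f (%d/%d)", prev, cd$n_in %||% NA_integer_,
                           cd$N %||% NA_integer_),
      reduction_pct = red,
      reduction_ci = if (!is.null(eff) && isTRUE(eff$estimable))
        sprintf("%.0f (%.0f, %.0f)", eff$reduction_pct, eff$reduction_lo,
                eff$reduction_hi) else NA_character_,
      interaction_p = ip,
      interaction_nominal = !is.na(ip) && ip < 0.10,
      n_secondary_enhanced = n_sec,
      q4w_consistent = q4w,
      incomplete = paste(incomplete, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-ifelse(is.na(out$n_secondary_enhanced), -1,
                       out$n_secondary_enhanced),
               -as.integer(out$interaction_nominal),
               -ifelse(is.na(out$reduction_pct), -Inf, out$reduction_pct))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
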