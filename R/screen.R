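# Question 1 screening: treatment-by-biomarker interaction tests, per-arm
# effect curves (linear NB and GAM smooth), and subgroup forests.

#' Treatment-by-biomarker interaction tests
#'
#' For each biomarker and each active arm (vs pooled placebo), fits a
#' separate NB model with treatment, region, age, prior-exacerbation
#' category, the biomarker and the treatment-by-biomarker interaction, and
#' reports the Wald p-value of the interaction. A joint likelihood-ratio
#' row compares the model carrying all five interaction terms against the
#' model with all five biomarker main effects but no interactions (5 df),
#' on participants complete for all biomarkers.
#'
#' @param data a prepared [trial_dataset()].
#' @param biomarkers biomarker columns (default the five candidates).
#' @param arms which active arms to test.
#' @param covariates adjustment covariates.
#' @param scale enter biomarkers raw (default) or log-transformed.
#' @return data.frame with one row per biomarker plus the joint LRT row,
#'   and one p-value column per arm.
#' @export
interaction_tests <- function(data, biomarkers = unname(BIOMARKER_COLS),
                              arms = c("q2w", "q4w"),
                              covariates = c("region", "age_years", "prior_cat"),
                              scale = c("raw", "log")) {
  scale <- match.arg(scale)
  stopifnot(inherits(data, "trial_dataset"))
  res <- data.frame(biomarker = c("all_lrt", biomarkers),
                    stringsAsFactors = FALSE)
  for (a in arms) {
    df <- arm_frame(data, a)
    if (scale == "log") {
      for (b in biomarkers) df[[b]] <- log(pmax(df[[b]], 1e-6))
    }
    pvals <- rep(NA_real_, length(biomarkers))
    for (i in seq_along(biomarkers)) {
      b <- biomarkers[i]
      if (length(unique(na.omit(df[[b]]))) < 2) next  # constant: row skipped
      f <- as.formula(paste("exacerbation_count ~ treat +",
                            paste(covariates, collapse = " + "),
                            "+", b, "+ treat:", b))
      p <- tryCatch({
        fit <- fit_nb(df, f)
        term <- paste0("treattralo:", b)
        bb <- fit$coefficients[term]
        se <- sqrt(fit$vcov[term, term])
        2 * pnorm(-abs(bb / se))
      }, error = function(e) NA_real_)
      pvals[i] <- p
    }
    joint <- tryCatch({
      cc <- complete.cases(df[, c(biomarkers, covariates,
                                  "exacerbation_count", "followup_years")])
      dfc <- df[cc, , drop = FALSE]
      base <- paste("exacerbation_count ~ treat +",
                    paste(covariates, collapse = " + "), "+",
                    paste(biomarkers, collapse = " + "))
      full <- fit_nb(dfc, as.formula(paste(base, "+",
                       paste(paste0("treat:", biomarkers), collapse = " + "))))
      redu <- fit_nb(dfc, as.formula(base))
      lr_test(full, redu, df = length(biomarkers))$p_value
    }, error = function(e) NA_real_)
    res[[paste0(a, "_p")]] <- c(joint, pvals)
  }
  res
}

#' Predicted exacerbation-rate curves over a biomarker
#'
#' Linear mode fits one NB model with a treatment-by-biomarker interaction
#' (plus adjustment covariates) and predicts the annualised rate per arm
#' over a grid spanning the 5th-95th sample quantiles of the biomarker, at
#' reference covariate values (modal category, median for continuous).
#' GAM mode fits per-arm penalised smooths of the biomarker
#' (`mgcv`, NB family), takes each participant's link prediction, smooths
#' it with a span-0.67 local linear regression per arm, and exponentiates.
#'
#' @param data prepared [trial_dataset()].
#' @param biomarker biomarker column.
#' @param mode `"linear"` or `"gam"`.
#' @param arm active arm vs pooled placebo.
#' @param covariates adjustment covariates.
#' @param n_grid grid size (linear mode).
#' @param span local-regression span (gam mode).
#' @param min_distinct minimum distinct biomarker values required.
#' @return data.frame (biomarker_value, arm, predicted_aaer) with the
#'   10th/90th percentiles as attributes `p10`/`p90` and, in linear mode,
#'   the per-arm log-slopes as attribute `log_slopes`.
#' @export
effect_curves <- function(data, biomarker, mode = c("linear", "gam"),
                          arm = "q2w",
                          covariates = c("region", "age_years", "prior_cat"),
                          n_grid = 100, span = 0.67, min_distinct = 10) {
  mode <- match.arg(mode)
  df <- arm_frame(data, arm)
  df <- df[!is.na(df[[biomarker]]), , drop = FALSE]
  if (length(unique(df[[biomarker]])) < min_distinct)
    stop("too few distinct biomarker values (< ", min_distinct, ")",
         call. = FALSE)
  qs <- quantile(df[[biomarker]], c(.05, .10, .90, .95), type = 7)

  if (mode == "linear") {
    f <- as.formula(paste("exacerbation_count ~ treat *", biomarker, "+",
                          paste(covariates, collapse = " + ")))
    fit <- fit_nb(df, f)
    grid <- seq(qs[[1]], qs[[4]], length.out = n_grid)
    nd <- expand.grid(bmv = grid, treat = c("placebo", "tralo"),
                      stringsAsFactors = FALSE)
    names(nd)[1] <- biomarker
    nd$treat <- factor(nd$treat, levels = c("placebo", "tralo"))
    for (cv in covariates) {
      nd[[cv]] <- if (is.numeric(df[[cv]])) median(df[[cv]], na.rm = TRUE) else {
        factor(modal_value(df[[cv]]), levels = levels(factor(df[[cv]])))
      }
    }
    nd$.log_exposure <- 0  # one participant-year
    pred <- predict(fit$fit, newdata = nd, type = "response")
    out <- data.frame(biomarker_value = nd[[biomarker]],
                      arm = as.character(nd$treat), predicted_aaer = pred,
                      stringsAsFactors = FALSE)
    cf <- fit$coefficients
    attr(out, "log_slopes") <- c(
      placebo = unname(cf[biomarker]),
      tralo = unname(cf[biomarker] + cf[paste0("treattralo:", biomarker)]))
  } else {
    df$.log_exposure <- log(df$followup_years)
    f <- as.formula(paste("exacerbation_count ~ treat +",
                          paste(covariates, collapse = " + "),
                          "+ s(", biomarker, ", by = treat)",
                          "+ offset(.log_exposure)"))
    gfit <- mgcv::gam(f, data = df, family = mgcv::nb(), method = "REML")
    link <- predict(gfit, type = "link") - df$.log_exposure
    keep <- df[[biomarker]] >= qs[[1]] & df[[biomarker]] <= qs[[4]]
    out <- do.call(rbind, lapply(c("placebo", "tralo"), function(a) {
      sel <- keep & df$treat == a
      lo <- loess(link[sel] ~ df[[biomarker]][sel], span = span, degree = 1)
      xs <- sort(unique(df[[biomarker]][sel]))
      data.frame(biomarker_value = xs, arm = a,
                 predicted_aaer = exp(predict(lo, newdata = xs)),
                 stringsAsFactors = FALSE)
    }))
  }
  attr(out, "p10") <- qs[[2]]
  attr(out, "p90") <- qs[[3]]
  rownames(out) <- NULL
  out
}

# Quartile assignment with type-7 quantiles; ties go to the lower quartile.
quartile_groups <- function(x) {
  qs <- quantile(x, c(.25, .5, .75), type = 7, na.rm = TRUE)
  cut(x, breaks = c(-Inf, unique(qs), Inf),
      labels = paste0("Q", seq_len(length(unique(qs)) + 1)), right = TRUE)
}

#' Forest of treatment effects in biomarker subgroups
#'
#' Quartile mode estimates the treatment effect inside each biomarker
#' quartile from a single NB model with a treatment-by-quartile interaction
#' plus adjustment covariates. Cumulative mode, for each quartile cut,
#' estimates effects above and below the cut from a model with a
#' treatment-by-side interaction. Effects are extracted as Wald contrasts.
#'
#' @param data prepared [trial_dataset()].
#' @param biomarker biomarker column.
#' @param mode `"quartile"` or `"cumulative"`.
#' @param arm active arm vs pooled placebo.
#' @param covariates adjustment covariates; `character(0)` for the
#'   unadjusted model.
#' @param cuts cumulative-mode cut-offs; default the three quartile cuts.
#' @param dispersion NULL (estimate k), 0 (Poisson) or fixed k.
#' @return data.frame, one row per subgroup effect (label, n_treated,
#'   n_control, rate_ratio, ci_low, ci_high, p_value, reduction_pct,
#'   reduction_lo, reduction_hi, estimable).
#' @export
subgroup_forest <- function(data, biomarker, mode = c("quartile", "cumulative"),
                            arm = "q2w",
                            covariates = c("region", "age_years", "prior_cat"),
                            cuts = NULL, dispersion = NULL) {
  mode <- match.arg(mode)
  df <- arm_frame(data, arm)
  df <- df[!is.na(df[[biomarker]]), , drop = FALSE]
  bmv <- df[[biomarker]]
  if (length(unique(bmv)) < 4)
    stop("need at least 4 distinct biomarker values", call. = FALSE)
  lab <- BIOMARKER_LABELS[biomarker]
  if (is.na(lab)) lab <- biomarker
  covs <- if (length(covariates))
    paste("+", paste(covariates, collapse = " + ")) else ""
  rows <- list()

  if (mode == "quartile") {
    df$.qgrp <- quartile_groups(bmv)
    qlv <- levels(df$.qgrp)
    f <- as.formula(paste("exacerbation_count ~ treat * .qgrp", covs))
    fit <- tryCatch(fit_nb(df, f, dispersion = dispersion),
                    error = function(e) NULL)
    for (q in qlv) {
      nt <- sum(df$.qgrp == q & df$treat == "tralo")
      nc <- sum(df$.qgrp == q & df$treat == "placebo")
      lbl <- sprintf("%s %s", lab, q)
      est <- if (is.null(fit) || nt == 0 || nc == 0) {
        non_estimable_effect(lbl, nt, nc)
      } else {
        w <- c(treattralo = 1)
        it <- paste0("treattralo:.qgrp", q)
        if (it %in% names(fit$coefficients)) w[it] <- 1
        tryCatch(effect_from_fit(fit, contrast = w, n_treated = nt,
                                 n_control = nc, label = lbl),
                 error = function(e) non_estimable_effect(lbl, nt, nc))
      }
      rows[[length(rows) + 1L]] <- as.data.frame(est)
    }
  } else {
    if (is.null(cuts))
      cuts <- unique(quantile(bmv, c(.25, .5, .75), type = 7))
    for (cv in cuts) {
      above <- bmv > cv
      for (side in c("above", "below")) {
        memb <- if (side == "above") above else !above
        nt <- sum(memb & df$treat == "tralo")
        nc <- sum(memb & df$treat == "placebo")
        lbl <- sprintf("%s %s %s (%s)", lab,
                       if (side == "above") ">" else "<=",
                       format(cv, digits = 4), side)
        est <- if (nt == 0 || nc == 0) {
          non_estimable_effect(lbl, nt, nc)
        } else if (all(above) || all(!above)) {
          # whole-population side: all-comers effect from the covariate model
          f0 <- as.formula(paste("exacerbation_count ~ treat", covs))
          tryCatch(effect_from_fit(fit_nb(df, f0, dispersion = dispersion),
                                   "treattralo",
                                   n_treated = nt, n_control = nc, label = lbl),
                   error = function(e) non_estimable_effect(lbl, nt, nc))
        } else {
          df$.side <- factor(ifelse(above, "above", "below"),
                             levels = c("below", "above"))
          f <- as.formula(paste("exacerbation_count ~ treat * .side", covs))
          tryCatch({
            fit <- fit_nb(df, f, dispersion = dispersion)
            w <- c(treattralo = 1)
            if (side == "above") w["treattralo:.sideabove"] <- 1
            effect_from_fit(fit, contrast = w, n_treated = nt,
                            n_control = nc, label = lbl)
          }, error = function(e) non_estimable_effect(lbl, nt, nc))
        }
        rows[[length(rows) + 1L]] <- as.data.frame(est)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
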