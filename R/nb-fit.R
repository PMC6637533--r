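# Negative-binomial regression core: exposure-offset NB fits (NB2,
# variance mu + k mu^2), Wald effect extraction on the rate-ratio scale,
# likelihood-ratio tests, and a fast treatment-only fitter for the
# thousands of small child-subgroup fits the subgroup search performs.

#' Fit a negative-binomial rate model with exposure offset
#'
#' Fits `formula` (a count outcome over arm/covariate/biomarker terms) by
#' maximum likelihood with NB2 dispersion (variance mu + k mu^2) and
#' `log(offset_var)` as exposure offset. `dispersion = NULL` estimates k
#' jointly; `dispersion = 0` gives a Poisson fit; a positive value fixes k.
#'
#' @param data a [trial_dataset()] or data.frame (rows with missing model
#'   variables are dropped, and `n_used` records how many remain).
#' @param formula model formula, e.g.
#'   `exacerbation_count ~ treat * feno_ppb + region + age_years + prior_cat`.
#' @param dispersion NULL (estimate k), 0 (Poisson) or fixed k > 0.
#' @param offset_var exposure column; its log enters as offset.
#' @return object of class `nb_fit`: coefficients, Wald covariance, `k`,
#'   `loglik`, `n_used`, `converged`, and the underlying glm fit.
#' @export
fit_nb <- function(data, formula, dispersion = NULL,
                   offset_var = "followup_years") {
  df <- if (inherits(data, "trial_dataset")) data$participants else data
  df <- as.data.frame(df)
  if (!offset_var %in% names(df))
    stop("offset variable not found: ", offset_var, call. = FALSE)
  df$.log_exposure <- log(df[[offset_var]])
  f <- update(formula, . ~ . + offset(.log_exposure))
  environment(f) <- environment()

  converged <- TRUE
  fit <- NULL
  if (is.null(dispersion)) {
    fit <- tryCatch(
      withCallingHandlers(
        MASS::glm.nb(f, data = df, maxit = 200),
        warning = function(w) {
          if (grepl("iteration limit|not converge", conditionMessage(w)))
            converged <<- FALSE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) {
      # degenerate likelihood in theta (e.g. all counts zero, or no
      # overdispersion at all): fall back to the Poisson boundary k -> 0
      converged <- FALSE
      fit <- suppressWarnings(glm(f, data = df, family = poisson()))
      k <- 0
    } else k <- 1 / fit$theta
  } else if (dispersion == 0) {
    fit <- suppressWarnings(glm(f, data = df, family = poisson()))
    k <- 0
  } else {
    fit <- suppressWarnings(
      glm(f, data = df, family = MASS::negative.binomial(theta = 1 / dispersion)))
    k <- dispersion
  }
  if (!isTRUE(fit$converged)) converged <- FALSE

  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficiency error: aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  V <- vcov(fit)
  ll <- if (is.null(dispersion)) as.numeric(logLik(fit)) else {
    mu <- fit$fitted.values
    yy <- fit$y
    if (k == 0) sum(stats::dpois(yy, mu, log = TRUE))
    else sum(stats::dnbinom(yy, mu = mu, size = 1 / k, log = TRUE))
  }
  structure(list(coefficients = cf, vcov = V, k = k, loglik = ll,
                 n_used = stats::nobs(fit), converged = converged,
                 fit = fit, formula = formula), class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("<nb_fit> n =", x$n_used, " k =", signif(x$k, 4),
      " logLik =", signif(x$loglik, 7),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  print(round(cbind(estimate = x$coefficients,
                    se = sqrt(diag(x$vcov))), 4))
  invisible(x)
}

#' Rate-ratio effect for a fitted term or contrast
#'
#' Maps a log-rate coefficient (or linear combination of coefficients) to a
#' rate ratio with 95% Wald CI, two-sided p-value, and the rate-reduction
#' percentage `(1 - RR) * 100` with its CI `(1 - ci_high, 1 - ci_low) * 100`.
#'
#' @param fit an [fit_nb()] result.
#' @param term coefficient name; or use `contrast` for a linear combination.
#' @param contrast named numeric vector of coefficient weights.
#' @param n_treated,n_control group sizes to carry along (optional).
#' @param label display label.
#' @return object of class `effect_estimate`.
#' @export
effect_from_fit <- function(fit, term = NULL, contrast = NULL,
                            n_treated = NA_integer_, n_control = NA_integer_,
                            label = NULL) {
  stopifnot(inherits(fit, "nb_fit") || is.list(fit))
  cf <- fit$coefficients
  V <- fit$vcov
  if (is.null(contrast)) {
    if (is.null(term) || !term %in% names(cf))
      stop("lookup error: term not in fit: ", term %||% "<NULL>", call. = FALSE)
    w <- setNames(numeric(length(cf)), names(cf))
    w[term] <- 1
    label <- label %||% term
  } else {
    w <- setNames(numeric(length(cf)), names(cf))
    miss <- setdiff(names(contrast), names(cf))
    if (length(miss))
      stop("lookup error: contrast names not in fit: ",
           paste(miss, collapse = ", "), call. = FALSE)
    w[names(contrast)] <- contrast
    label <- label %||% "contrast"
  }
  b <- sum(w * cf)
  se <- sqrt(drop(t(w) %*% V %*% w))
  z <- b / se
  effect_estimate(rate_ratio = exp(b), ci_low = exp(b - 1.96 * se),
                  ci_high = exp(b + 1.96 * se),
                  p_value = 2 * pnorm(-abs(z)),
                  n_treated = n_treated, n_control = n_control,
                  label = label, log_rr = b, se = se)
}

effect_estimate <- function(rate_ratio, ci_low, ci_high, p_value,
                            n_treated = NA_integer_, n_control = NA_integer_,
                            label = "", log_rr = log(rate_ratio), se = NA_real_,
                            estimable = TRUE) {
  structure(list(
    label = label, rate_ratio = rate_ratio, ci_low = ci_low,
    ci_high = ci_high, p_value = p_value,
    reduction_pct = (1 - rate_ratio) * 100,
    reduction_lo = (1 - ci_high) * 100,
    reduction_hi = (1 - ci_low) * 100,
    n_treated = n_treated, n_control = n_control,
    log_rr = log_rr, se = se, estimable = estimable), class = "effect_estimate")
}

non_estimable_effect <- function(label = "", n_treated = NA_integer_,
                                 n_control = NA_integer_) {
  effect_estimate(NA_real_, NA_real_, NA_real_, NA_real_,
                  n_treated, n_control, label, NA_real_, NA_real_,
                  estimable = FALSE)
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat("<effect> ", x$label, ": non-estimable\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("<effect> %s: RR %.2f (%.2f, %.2f), reduction %.0f%% (%.0f, %.0f), p = %.3g\n",
              x$label, x$rate_ratio, x$ci_low, x$ci_high,
              x$reduction_pct, x$reduction_lo, x$reduction_hi, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(label = x$label, n_treated = x$n_treated,
             n_control = x$n_control, rate_ratio = x$rate_ratio,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
             reduction_pct = x$reduction_pct, reduction_lo = x$reduction_lo,
             reduction_hi = x$reduction_hi, estimable = x$estimable,
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test of nested NB fits
#'
#' @param full,reduced [fit_nb()] results on the same rows (`n_used` must
#'   agree; silent case-deletion differences would make the test
#'   meaningless).
#' @param df degrees of freedom; defaults to the difference in number of
#'   mean-model coefficients.
#' @return list (statistic, df, p_value).
#' @export
lr_test <- function(full, reduced, df = NULL) {
  if (full$n_used != reduced$n_used)
    stop("lr_test: fits use different rows (n_used ", full$n_used, " vs ",
         reduced$n_used, "); align missing data first", call. = FALSE)
  df <- df %||% (length(full$coefficients) - length(reduced$coefficients))
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < 0 && stat > -1e-6) stat <- 0
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

# ---- fast treatment-only NB fit ---------------------------------------------

# Intercept + binary treatment NB2 fit with log-exposure offset. The mean
# model is saturated (one rate per group), so the fit alternates exact
# per-group Newton solves of the rate score with Newton/bisection ML
# updates of theta. Hand-rolled because the subgroup search, bootstrap and
# permutation null run this tens of thousands of times on small child
# subgroups; it is cross-checked against glm.nb and a (beta, k) grid
# oracle in the tests.
nb_fit_counts <- function(y, log_offset, treat, max_round = 25, tol = 1e-10) {
  n <- length(y)
  g <- as.logical(treat)
  out <- list(beta0 = NA_real_, beta_treat = NA_real_, se_treat = NA_real_,
              k = NA_real_, loglik = NA_real_, n = n, converged = FALSE)
  if (n < 2 || !any(g) || all(g)) return(out)
  if (all(y == 0) || all(y[g] == 0) || all(y[!g] == 0))
    return(out)  # a zero-event group: log rate ratio unbounded

  t_exp <- exp(log_offset)
  # per-group rate score for fixed theta: sum (y - mu)/(1 + mu/theta) = 0,
  # mu_i = lambda * t_i; Newton in eta = log(lambda)
  solve_rate <- function(yy, tt, theta, eta) {
    for (it in 1:30) {
      mu <- tt * exp(eta)
      r <- 1 + mu / theta
      sc <- sum((yy - mu) / r)
      info <- sum(mu * (1 + yy / theta) / r^2)
      if (info <= 0) break
      step <- sc / info
      eta <- eta + step
      if (abs(step) < 1e-12) break
    }
    eta
  }
  # ML theta score (given mu): standard digamma form
  theta_score <- function(theta, yy, mu) {
    sum(digamma(yy + theta) - digamma(theta) + log(theta) + 1 -
          log(theta + mu) - (yy + theta) / (theta + mu))
  }
  eta0 <- log(sum(y[!g]) / sum(t_exp[!g]))
  eta1 <- log(sum(y[g]) / sum(t_exp[g]))
  theta <- 1
  ll_old <- -Inf
  for (r in seq_len(max_round)) {
    eta0 <- solve_rate(y[!g], t_exp[!g], theta, eta0)
    eta1 <- solve_rate(y[g], t_exp[g], theta, eta1)
    mu <- t_exp * exp(ifelse(g, eta1, eta0))
    # Newton on log(theta), guarded
    for (it in 1:20) {
      sc <- theta_score(theta, y, mu)
      h <- theta * 1e-4
      d <- (theta_score(theta + h, y, mu) - sc) / h
      if (!is.finite(sc) || !is.finite(d) || d >= 0) break
      step <- sc / d
      new_theta <- theta - step
      if (new_theta <= 0) new_theta <- theta / 2
      if (new_theta > 1e7) { new_theta <- 1e7; theta <- new_theta; break }
      if (abs(log(new_theta / theta)) < 1e-10) { theta <- new_theta; break }
      theta <- new_theta
    }
    ll <- sum(stats::dnbinom(y, mu = mu, size = theta, log = TRUE))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  b0 <- eta0
  b1 <- eta1 - eta0
  if (!is.finite(b0) || !is.finite(b1) || abs(b1) > 15) return(out)
  # Wald variance from the working weights w = mu/(1 + mu/theta)
  w <- mu / (1 + mu / theta)
  v1 <- 1 / sum(w[g]) + 1 / sum(w[!g])
  out$beta0 <- b0
  out$beta_treat <- b1
  out$se_treat <- sqrt(v1)
  out$k <- 1 / theta
  out$loglik <- ll
  out$converged <- TRUE
  out
}

# Treatment-benefit z (positive = fewer events on treatment) and reduction
# from a fast treatment-only fit on a participant subset.
treat_only_effect <- function(df) {
  f <- nb_fit_counts(df$exacerbation_count, log(df$followup_years),
                     as.integer(df$treat == "tralo"))
  if (!f$converged) return(list(ok = FALSE))
  list(ok = TRUE, z = -f$beta_treat / f$se_treat,
       log_rr = f$beta_treat, se = f$se_treat,
       reduction_pct = (1 - exp(f$beta_treat)) * 100,
       p_one_sided = pnorm(f$beta_treat / f$se_treat),
       p_two_sided = 2 * pnorm(-abs(f$beta_treat / f$se_treat)),
       n = f$n, k = f$k, loglik = f$loglik)
}
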