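#' Cox proportional-hazards fit
#'
#' Maximizes the Efron-tie-corrected partial likelihood (via the survival
#' machinery), returning coefficients, hazard ratios, Wald statistics, the
#' log partial likelihood and the Breslow baseline cumulative hazard.
#'
#' @param x sample x covariate numeric matrix or data frame.
#' @param time follow-up times (> 0).
#' @param event 0/1 event indicator.
#' @return object of class `cox_fit`: list with `coefficients`,
#'   `hazard_ratio`, `se`, `p_value` (named vectors), `loglik`, `baseline`
#'   (tibble time, cumhaz), `n`, `n_event`, and the underlying `model`.
#' @export
cox_fit <- function(x, time, event) {
  x <- as.data.frame(x)
  if (any(!event %in% c(0, 1))) {
    stop_pairsig("`event` must be 0/1.", "pairsig_validation_error")
  }
  if (sum(event) < 1) {
    stop_pairsig("Cox fit needs at least one event.", "pairsig_validation_error")
  }
  if (any(time <= 0)) {
    stop_pairsig("`time` must be positive.", "pairsig_validation_error")
  }
  const <- vapply(x, function(v) sd(as.numeric(v)) == 0, TRUE)
  if (any(const)) {
    stop_pairsig(paste0("Covariate(s) constant across samples: ",
                        paste(names(x)[const], collapse = ", ")),
                 "pairsig_validation_error")
  }
  dat <- cbind(x, .time = time, .event = event)
  separation <- NULL
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ .,
                    data = dat[, c(names(x), ".time", ".event")],
                    ties = "efron", x = FALSE,
                    control = survival::coxph.control(eps = 1e-11, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        separation <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    })
  sfit <- summary(fit)
  if (!is.null(separation) || any(abs(coef(fit)) > 15) ||
      any(!is.finite(sfit$coefficients[, "se(coef)"]))) {
    worst <- names(coef(fit))[which.max(abs(coef(fit)))]
    stop_pairsig(sprintf("Monotone likelihood (perfect separation) on covariate '%s'.",
                         worst), "pairsig_separation_error")
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(
    coefficients = coef(fit),
    hazard_ratio = exp(coef(fit)),
    se = sfit$coefficients[, "se(coef)"],
    p_value = sfit$coefficients[, "Pr(>|z|)"],
    loglik = fit$loglik[2],
    baseline = tibble::tibble(time = bh$time, cumhaz = bh$hazard),
    n = fit$n, n_event = fit$nevent,
    model = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, log partial likelihood = %.3f\n",
              x$n, x$n_event, x$loglik))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 hazard_ratio = unname(x$hazard_ratio),
                 std_error = unname(x$se),
                 p_value = unname(x$p_value))
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, loglik = x$loglik,
                 concordance = unname(x$model$concordance["concordance"]))
}

#' Univariate Cox screen over gene-pair indicators
#'
#' Fits a single-covariate Cox model per pair and keeps pairs with Wald
#' `p < p_max`. Pairs whose fit fails (e.g. separation) are dropped with a
#' warning rather than aborting the screen.
#'
#' @param pim pairs x samples 0/1 matrix.
#' @param time,event survival outcome, aligned to the columns of `pim`.
#' @param p_max Wald p-value threshold (default 0.05).
#' @param keep_all return all pairs with a `kept` flag instead of survivors
#'   only.
#' @return tibble (pair_label, coefficient, hazard_ratio, std_error,
#'   p_value), survivors only unless `keep_all`.
#' @export
univariate_screen <- function(pim, time, event, p_max = 0.05,
                              keep_all = FALSE) {
  if (nrow(pim) == 0) {
    return(tibble::tibble(pair_label = character(), coefficient = numeric(),
                          hazard_ratio = numeric(), std_error = numeric(),
                          p_value = numeric()))
  }
  n_failed <- 0L
  y <- survival::Surv(time, event)
  rows <- lapply(rownames(pim), function(lbl) {
    # lightweight single-covariate fit (same Efron likelihood as cox_fit,
    # without the baseline-hazard bookkeeping)
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ x, data = data.frame(x = pim[lbl, ]),
                                       ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)) || abs(coef(fit)) > 15) {
      n_failed <<- n_failed + 1L
      return(NULL)
    }
    se <- sqrt(diag(fit$var))
    tibble::tibble(pair_label = lbl,
                   coefficient = unname(coef(fit)),
                   hazard_ratio = unname(exp(coef(fit))),
                   std_error = unname(se),
                   p_value = unname(2 * pnorm(-abs(coef(fit) / se))))
  })
  if (n_failed > 0) {
    warn(sprintf("%d pair(s) dropped from the univariate screen (fit failure).",
                 n_failed))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$kept <- out$p_value < p_max
  if (!keep_all) {
    out <- out[out$kept, , drop = FALSE]
    out$kept <- NULL
  }
  out
}

#' Lasso-penalized Cox regression with repeated cross-validation
#'
#' Coordinate-descent solution path over a geometric penalty grid (100 points
#' from the smallest all-zero penalty down to 0.01 of it), with the penalty
#' chosen from the cross-validated partial-likelihood deviance averaged over
#' `n_repeats` independent fold splits. The default `cv_rule = "1se"` takes
#' the largest penalty within one standard error of the deviance minimum:
#' after a univariate screen on the same data, the deviance minimum inherits
#' the screen's selection bias and admits many null covariates, while the
#' one-standard-error rule returns an empty or near-empty signature on null
#' data at a modest cost in sensitivity. `cv_rule = "min"` gives the plain
#' deviance minimizer. Covariates are standardized internally; coefficients
#' are reported on the original scale and zero coefficients dropped.
#'
#' @param x sample x covariate matrix.
#' @param time,event survival outcome.
#' @param n_folds CV folds (must not exceed the event count).
#' @param n_repeats repeated fold splits averaged for penalty selection.
#' @param cv_rule `"1se"` (default) or `"min"`, see Details.
#' @param seed optional integer seed for the fold splits.
#' @param nlambda,lambda_min_ratio penalty-grid geometry.
#' @param lambda_fixed skip cross-validation and report the coefficients at
#'   this penalty (0 gives the unpenalized partial-likelihood fit).
#' @return list with `coefficients` (named nonzero vector), `lambda`
#'   (selected penalty), `cv` (tibble lambda, mean_deviance; `NULL` when
#'   `lambda_fixed` is used), `fit` (the glmnet path object).
#' @export
lasso_cox <- function(x, time, event, n_folds = 10, n_repeats = 25,
                      seed = NULL, cv_rule = c("1se", "min"), nlambda = 100,
                      lambda_min_ratio = 0.01, lambda_fixed = NULL) {
  cv_rule <- match.arg(cv_rule)
  x <- as.matrix(x)
  if (is.null(lambda_fixed) && sum(event) < n_folds) {
    stop_pairsig(sprintf("Only %d events for %d folds; reduce `n_folds`.",
                         sum(event), n_folds), "pairsig_validation_error")
  }
  y <- survival::Surv(time, event)
  path <- glmnet::glmnet(x, y, family = "cox", nlambda = nlambda,
                         lambda.min.ratio = lambda_min_ratio,
                         thresh = 1e-12)
  lambda_grid <- path$lambda
  if (!is.null(lambda_fixed)) {
    # refit a path that terminates exactly at the requested penalty, so the
    # reported coefficients are a converged solution, not an interpolation
    lam <- sort(unique(c(lambda_grid[lambda_grid > lambda_fixed],
                         lambda_fixed)), decreasing = TRUE)
    refit <- glmnet::glmnet(x, y, family = "cox", lambda = lam,
                            thresh = 1e-12)
    beta <- as.vector(coef(refit, s = lambda_fixed))
    names(beta) <- colnames(x)
    return(list(coefficients = beta[beta != 0], lambda = lambda_fixed,
                cv = NULL, fit = refit))
  }
  if (!is.null(seed)) {
    return(with_preserved_rng({
      set.seed(as.integer(seed))
      lasso_cox(x, time, event, n_folds = n_folds, n_repeats = n_repeats,
                seed = NULL, cv_rule = cv_rule, nlambda = nlambda,
                lambda_min_ratio = lambda_min_ratio)
    }))
  }
  n <- nrow(x)
  cvm <- matrix(NA_real_, n_repeats, length(lambda_grid))
  cvsd <- matrix(NA_real_, n_repeats, length(lambda_grid))
  for (r in seq_len(n_repeats)) {
    foldid <- sample(rep(seq_len(n_folds), length.out = n))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                            lambda = lambda_grid)
    cvm[r, seq_along(cv$cvm)] <- cv$cvm
    cvsd[r, seq_along(cv$cvsd)] <- cv$cvsd
  }
  mean_dev <- colMeans(cvm, na.rm = TRUE)
  mean_sd <- colMeans(cvsd, na.rm = TRUE)
  best <- which.min(mean_dev)
  lambda <- if (cv_rule == "min") {
    lambda_grid[best]
  } else {
    max(lambda_grid[mean_dev <= mean_dev[best] + mean_sd[best]])
  }
  beta <- as.vector(coef(path, s = lambda))
  names(beta) <- colnames(x)
  list(coefficients = beta[beta != 0],
       lambda = lambda,
       cv = tibble::tibble(lambda = lambda_grid, mean_deviance = mean_dev),
       fit = path)
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator with Greenwood standard errors, returned as a
#' tidy step-function table.
#'
#' @param time follow-up times (>= 0).
#' @param event 0/1 event indicator.
#' @return tibble (time, n_risk, n_event, n_censor, surv, std_err, lower,
#'   upper), one row per distinct observed time.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) {
    stop_pairsig("Negative survival times.", "pairsig_validation_error")
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "log")
  tibble::tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 n_censor = sf$n.censor, surv = sf$surv,
                 std_err = sf$surv * sf$std.err,
                 lower = sf$lower, upper = sf$upper)
}

km_surv_at <- function(time, event, at) {
  # right-continuous KM evaluated at `at`, with Greenwood CI
  km <- km_estimate(time, event)
  idx <- findInterval(at, km$time)
  if (idx == 0) return(c(surv = 1, lower = 1, upper = 1))
  c(surv = km$surv[idx], lower = km$lower[idx], upper = km$upper[idx])
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' referred to a chi-squared distribution with `groups - 1` degrees of
#' freedom.
#'
#' @param groups group label per sample (>= 2 non-empty groups).
#' @param time,event survival outcome.
#' @return tibble (statistic, df, p_value).
#' @export
logrank_test <- function(groups, time, event) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2 || any(table(groups) == 0)) {
    stop_pairsig("Log-rank needs at least two non-empty groups.",
                 "pairsig_validation_error")
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- nlevels(groups) - 1
  tibble::tibble(statistic = sd_$chisq, df = df,
                 p_value = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

censor_surv_km <- function(time, event) {
  # KM of the censoring distribution (event roles flipped)
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  list(times = sf$time, surv = sf$surv)
}

censor_surv_eval <- function(cs, at, left = FALSE) {
  # step-function evaluation; left = TRUE gives the left limit G(t-)
  tt <- if (left) cs$times < at else cs$times <= at
  idx <- sum(tt)
  if (idx == 0) 1 else cs$surv[idx]
}

#' Time-dependent ROC for a prognostic score
#'
#' Cumulative-case / dynamic-control ROC at horizon `t`: cases are subjects
#' with an observed event by `t`, controls are subjects still at risk beyond
#' `t`. Censoring is handled by inverse-probability-of-censoring weights from
#' the Kaplan-Meier estimate of the censoring distribution (cases weighted by
#' `1/G(T_i^-)`, controls by `1/G(t)`), which redistributes censored mass in
#' the KM fashion; with no censoring before `t` the curve reduces to the
#' empirical ROC of the binary event-by-t outcome. AUC is the trapezoidal
#' integral of the curve; the best cutoff maximizes Youden's
#' `J = sensitivity + specificity - 1` (ties broken toward the lower cutoff).
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param time,event survival outcome.
#' @param horizon evaluation time `t` within the observed follow-up.
#' @return object of class `td_roc`: list with `horizon`, `curve` (tibble:
#'   cutoff, sensitivity, specificity), `auc`, `best_cutoff`.
#' @export
time_dependent_roc <- function(scores, time, event, horizon) {
  assert_scalar_number(horizon, "horizon", lower = 0, strict_lower = TRUE)
  is_case <- time <= horizon & event == 1
  is_control <- time > horizon
  if (!any(is_case)) {
    stop_pairsig(sprintf("No observed events by t = %g; ROC undefined (no cases).", horizon),
                 "pairsig_validation_error")
  }
  if (!any(is_control)) {
    stop_pairsig(sprintf("No subjects at risk beyond t = %g; ROC undefined (no controls).", horizon),
                 "pairsig_validation_error")
  }
  cs <- censor_surv_km(time, event)
  w <- numeric(length(scores))
  w[is_case] <- 1 / vapply(time[is_case], function(ti)
    censor_surv_eval(cs, ti, left = TRUE), 0)
  w[is_control] <- 1 / censor_surv_eval(cs, horizon)
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(cc)
    sum(w[is_case & scores > cc]) / sum(w[is_case]), 0)
  spec <- vapply(cuts, function(cc)
    sum(w[is_control & scores <= cc]) / sum(w[is_control]), 0)
  curve <- tibble::tibble(cutoff = cuts, sensitivity = sens,
                          specificity = spec)
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- sens + spec - 1
  best <- cuts[which(j == max(j))]
  structure(list(horizon = horizon, curve = curve, auc = auc,
                 best_cutoff = min(best)), class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("<td_roc> t = %g: AUC = %.3f, best cutoff (Youden) = %.4g\n",
              x$horizon, x$auc, x$best_cutoff))
  invisible(x)
}

#' @export
tidy.td_roc <- function(x, ...) x$curve

#' @export
glance.td_roc <- function(x, ...) {
  tibble::tibble(horizon = x$horizon, auc = x$auc,
                 best_cutoff = x$best_cutoff)
}

#' Harrell's concordance index
#'
#' Fraction of usable (comparable) subject pairs in which the higher risk
#' score belongs to the subject failing earlier; score ties count 0.5, and
#' pairs whose ordering is hidden by censoring are excluded.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param time,event survival outcome.
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(scores, time, event) {
  cc <- survival::concordance(survival::Surv(time, event) ~ scores,
                              reverse = TRUE)
  n_comparable <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (!is.finite(cc$concordance) || n_comparable == 0) {
    stop_pairsig("No comparable subject pairs; concordance undefined.",
                 "pairsig_validation_error")
  }
  unname(cc$concordance)
}
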