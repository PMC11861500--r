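#' Fit a point-based nomogram over a Cox model
#'
#' Maps each covariate's contribution to the Cox linear predictor onto a
#' 0-100 point scale: per covariate `j`, `points_j(x) = 100 * beta_j *
#' (x_j - ref_j) / max_k |beta_k * range_k|`, with the reference `ref_j`
#' chosen as the observed covariate value minimizing `beta_j * x_j` so every
#' point contribution is non-negative; the covariate with the largest
#' `|beta * range|` spans exactly 0-100. Total points map back to the linear
#' predictor by an affine transform, and survival probabilities come from
#' the Breslow baseline: `S(t | x) = S_ref(t)^exp(lp(x) - lp_ref)`.
#'
#' @param cox a [cox_fit()] fitted on `data`.
#' @param data data frame holding the model covariates (numeric; code
#'   factors beforehand, e.g. TNM as 1-4, gender as 0/1).
#' @param horizons prediction horizons, same time unit as the fit (default
#'   1/3/5 years in days).
#' @return object of class `nomogram_model`.
#' @export
fit_nomogram <- function(cox, data, horizons = c(1, 3, 5) * 365.25) {
  stopifnot(inherits(cox, "cox_fit"))
  beta <- cox$coefficients
  covs <- names(beta)
  missing <- setdiff(covs, names(data))
  if (length(missing)) {
    stop_pairsig(paste0("`data` lacks model covariates: ",
                        paste(missing, collapse = ", ")),
                 "pairsig_validation_error")
  }
  x <- as.matrix(as.data.frame(data)[, covs, drop = FALSE])
  rng <- apply(x, 2, function(v) diff(range(v)))
  maxscale <- max(abs(beta * rng))
  if (maxscale == 0) {
    stop_pairsig("All covariates have zero effect range; nomogram undefined.",
                 "pairsig_validation_error")
  }
  ref <- vapply(covs, function(j) {
    vals <- range(x[, j])
    vals[which.min(beta[j] * vals)]
  }, 0)
  last_event <- max(cox$baseline$time[cox$baseline$cumhaz > 0], na.rm = TRUE)
  if (any(horizons > max(cox$baseline$time))) {
    stop_pairsig("A prediction horizon lies beyond the observed follow-up.",
                 "pairsig_validation_error")
  }
  lp_ref <- sum(beta * ref)
  structure(list(
    coefficients = beta, reference = ref, maxscale = maxscale,
    baseline = cox$baseline, lp_ref = lp_ref, horizons = horizons,
    covariates = covs), class = "nomogram_model")
}

#' @export
print.nomogram_model <- function(x, ...) {
  cat("<nomogram_model> covariate points per unit:\n")
  print(round(100 * x$coefficients / x$maxscale, 2))
  cat(sprintf("horizons: %s\n", paste(x$horizons, collapse = ", ")))
  invisible(x)
}

nomogram_points <- function(model, data) {
  x <- as.matrix(as.data.frame(data)[, model$covariates, drop = FALSE])
  pts <- sweep(x, 2, model$reference) %*% diag(model$coefficients,
                                               length(model$coefficients))
  pts <- 100 * pts / model$maxscale
  colnames(pts) <- model$covariates
  pts
}

baseline_cumhaz_at <- function(baseline, at) {
  idx <- findInterval(at, baseline$time)
  ifelse(idx == 0, 0, baseline$cumhaz[pmax(idx, 1)])
}

#' Predict from a nomogram model
#'
#' @param object a [fit_nomogram()] model.
#' @param newdata data frame with the model covariates.
#' @param type `"survival"` (matrix samples x horizons), `"points"`
#'   (per-covariate points plus total), or `"lp"` (Cox linear predictor).
#' @param horizons horizons for `type = "survival"`; defaults to the model's.
#' @param ... unused.
#' @export
predict.nomogram_model <- function(object, newdata, type = c("survival", "points", "lp"),
                                   horizons = NULL, ...) {
  type <- match.arg(type)
  pts <- nomogram_points(object, newdata)
  total <- rowSums(pts)
  lp <- total * object$maxscale / 100 + object$lp_ref
  if (type == "points") {
    out <- tibble::as_tibble(pts)
    out$total <- total
    return(out)
  }
  if (type == "lp") return(lp)
  horizons <- horizons %||% object$horizons
  h0 <- baseline_cumhaz_at(object$baseline, horizons)
  surv <- exp(-outer(exp(lp), h0))
  colnames(surv) <- paste0("t", horizons)
  surv
}

#' Calibration curve of nomogram-predicted survival
#'
#' Samples are binned by quantiles of their predicted survival probability at
#' `t`; per bin, the mean prediction is compared with the Kaplan-Meier
#' observed survival at `t` (Greenwood confidence interval). Bins whose
#' subjects are all censored before `t` are flagged rather than fabricated.
#'
#' @param model a [fit_nomogram()] model.
#' @param data data frame with the model covariates.
#' @param time,event survival outcome aligned to `data`.
#' @param t evaluation horizon.
#' @param n_bins number of quantile bins (default 3).
#' @return tibble (bin, n, predicted, observed, lower, upper, flagged).
#' @export
calibration_curve <- function(model, data, time, event, t, n_bins = 3) {
  pred <- predict(model, data, type = "survival", horizons = t)[, 1]
  if (n_bins > length(unique(pred))) {
    stop_pairsig(sprintf("`n_bins` = %d exceeds the %d distinct predictions.",
                         n_bins, length(unique(pred))),
                 "pairsig_validation_error")
  }
  if (n_bins == 1) {
    breaks <- range(pred) + c(-1e-9, 1e-9)
  } else {
    breaks <- unique(quantile(pred, seq(0, 1, length.out = n_bins + 1)))
    breaks[1] <- breaks[1] - 1e-9
    breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  }
  bin <- cut(pred, breaks = breaks, labels = FALSE, include.lowest = TRUE)
  rows <- lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    degenerate <- all(event[idx] == 0 & time[idx] < t)
    if (degenerate) {
      return(tibble::tibble(bin = b, n = sum(idx),
                            predicted = mean(pred[idx]), observed = NA_real_,
                            lower = NA_real_, upper = NA_real_,
                            flagged = TRUE))
    }
    km <- km_surv_at(time[idx], event[idx], t)
    tibble::tibble(bin = b, n = sum(idx), predicted = mean(pred[idx]),
                   observed = unname(km["surv"]), lower = unname(km["lower"]),
                   upper = unname(km["upper"]), flagged = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Bootstrap concordance of a risk score
#'
#' Resamples subjects with replacement `B` times, computes Harrell's C-index
#' per resample and reports the mean with a 2.5/97.5 percentile interval.
#' Degenerate resamples with no comparable pairs are redrawn (capped at
#' `10 * B` total draws).
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param time,event survival outcome.
#' @param B number of bootstrap resamples (>= 10).
#' @param seed optional integer seed.
#' @return tibble (estimate, conf_low, conf_high, B, n_redrawn).
#' @export
bootstrap_cindex <- function(scores, time, event, B = 1000, seed = NULL) {
  if (B < 10) {
    stop_pairsig("`B` must be at least 10.", "pairsig_validation_error")
  }
  run <- function() {
    n <- length(scores)
    cs <- numeric(B)
    redrawn <- 0L
    draws <- 0L
    b <- 1L
    while (b <= B) {
      draws <- draws + 1L
      if (draws > 10L * B) {
        stop_pairsig("Too many degenerate bootstrap resamples (no comparable pairs).",
                     "pairsig_validation_error")
      }
      idx <- sample.int(n, n, replace = TRUE)
      ci <- tryCatch(concordance_index(scores[idx], time[idx], event[idx]),
                     error = function(e) NA_real_)
      if (is.na(ci)) {
        redrawn <- redrawn + 1L
        next
      }
      cs[b] <- ci
      b <- b + 1L
    }
    qs <- quantile(cs, c(0.025, 0.975), names = FALSE)
    tibble::tibble(estimate = mean(cs), conf_low = qs[1], conf_high = qs[2],
                   B = B, n_redrawn = redrawn)
  }
  if (!is.null(seed)) {
    with_preserved_rng({
      set.seed(as.integer(seed))
      run()
    })
  } else {
    run()
  }
}
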