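#' Remove genes undetected in too many samples
#'
#' A gene counts as detected in a sample when its value is strictly positive.
#' A gene is removed when its undetected fraction strictly exceeds
#' `max_undetected_frac` in ANY of the provided cohorts (training plus any
#' validation cohorts), so a gene must be reliably measured everywhere it
#' will be used. Gene order is preserved.
#'
#' @param expr genes x samples matrix (the training cohort).
#' @param ... additional cohorts (matrices) that must also pass the filter;
#'   cohorts lacking a gene do not veto it.
#' @param max_undetected_frac maximum tolerated undetected fraction
#'   (default 0.10; removal requires strictly more).
#' @return the filtered matrix.
#' @export
filter_detected <- function(expr, ..., max_undetected_frac = 0.10) {
  assert_expression_matrix(expr)
  assert_scalar_number(max_undetected_frac, "max_undetected_frac", 0, 1)
  cohorts <- c(list(expr), list(...))
  keep <- rep(TRUE, nrow(expr))
  names(keep) <- rownames(expr)
  for (m in cohorts) {
    assert_expression_matrix(m)
    shared <- intersect(rownames(expr), rownames(m))
    frac <- rowMeans(m[shared, , drop = FALSE] <= 0)
    keep[shared][frac[shared] > max_undetected_frac] <- FALSE
  }
  if (!any(keep)) {
    stop_pairsig("All genes failed the detection filter; review `max_undetected_frac` or the input scale.",
                 "pairsig_validation_error")
  }
  expr[keep, , drop = FALSE]
}

#' Two-group differential expression on log2-scale values
#'
#' Per-gene Welch two-sample t-test between the `group = 1` (e.g. mutant) and
#' `group = 0` (wild-type) samples, with `log2fc = mean(group 1) -
#' mean(group 0)` (the values are assumed already log2-like, so the mean
#' difference is the log2 fold change). A gene passes when `p_value <
#' p_thresh` AND `|log2fc| > lfc_thresh`.
#'
#' An optional empirical-Bayes variance-shrinkage mode squeezes the per-gene
#' pooled variances toward their across-gene mean (method-of-moments prior
#' weight), for sensitivity analysis on small groups.
#'
#' @param expr genes x samples matrix (log2 scale).
#' @param group 0/1 vector over samples (1 = mutant).
#' @param p_thresh,lfc_thresh decision thresholds (defaults 0.05 and 0.5).
#' @param shrink_var use the empirical-Bayes moderated variance.
#' @param adjust apply Benjamini-Hochberg adjustment before thresholding.
#' @return tibble (gene, log2fc, p_value, direction, passed), sorted by
#'   p-value ascending.
#' @export
differential_expression <- function(expr, group, p_thresh = 0.05,
                                    lfc_thresh = 0.5, shrink_var = FALSE,
                                    adjust = FALSE) {
  assert_expression_matrix(expr)
  group <- as.integer(group)
  if (length(group) != ncol(expr) || !all(group %in% c(0L, 1L))) {
    stop_pairsig("`group` must be a 0/1 vector with one label per sample.",
                 "pairsig_validation_error")
  }
  n1 <- sum(group == 1)
  n0 <- sum(group == 0)
  if (n1 < 2 || n0 < 2) {
    stop_pairsig("Each group needs at least 2 samples (variance undefined otherwise).",
                 "pairsig_validation_error")
  }
  x1 <- expr[, group == 1, drop = FALSE]
  x0 <- expr[, group == 0, drop = FALSE]
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  if (shrink_var) {
    # squeeze each group variance toward its across-gene mean with weight
    # proportional to the prior df implied by the variance of variances
    squeeze <- function(v, n) {
      s2bar <- mean(v)
      d <- n - 1
      excess <- max(var(v) - 2 * s2bar^2 / d, 0)
      d0 <- if (excess > 0) 2 * s2bar^2 / excess else Inf
      if (is.finite(d0)) (d0 * s2bar + d * v) / (d0 + d) else rep(s2bar, length(v))
    }
    v1 <- squeeze(v1, n1)
    v0 <- squeeze(v0, n0)
  }
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m0[se2 == 0], 1, 0)
  log2fc <- m1 - m0
  p_used <- if (adjust) stats::p.adjust(p, "BH") else p
  res <- tibble::tibble(
    gene = rownames(expr),
    log2fc = unname(log2fc),
    p_value = unname(p),
    direction = dplyr::case_when(log2fc > 0 ~ "up",
                                 log2fc < 0 ~ "down",
                                 TRUE ~ NA_character_),
    passed = p_used < p_thresh & abs(log2fc) > lfc_thresh)
  dplyr::arrange(res, .data$p_value)
}
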