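#' Build relative-rank gene-pair indicators
#'
#' For every unordered combination of the requested genes (ordered
#' alphabetically within the pair, and pairs listed lexicographically), the
#' per-sample indicator is 1 when the first gene's expression strictly
#' exceeds the second's and 0 otherwise (ties are 0). Because the indicator
#' depends only on the within-sample ordering of two genes, it is invariant
#' under any per-sample strictly increasing transform of the expression —
#' the property that removes between-sample measurement/normalization
#' effects.
#'
#' @param expr genes x samples matrix.
#' @param genes character vector of gene symbols to pair (>= 2, all measured).
#' @return numeric 0/1 matrix, `choose(n, 2)` pairs x samples, rownames
#'   `"GENEA|GENEB"`.
#' @export
build_pairs <- function(expr, genes) {
  assert_expression_matrix(expr)
  genes <- unique(genes)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop_pairsig(paste0("Requested genes absent from expression: ",
                        paste(missing, collapse = ", ")),
                 "pairsig_validation_error")
  }
  if (length(genes) < 2) {
    stop_pairsig("Need at least 2 genes to build pairs.",
                 "pairsig_validation_error")
  }
  genes <- sort(genes)
  idx <- combn(length(genes), 2)
  a <- genes[idx[1, ]]
  b <- genes[idx[2, ]]
  pim <- (expr[a, , drop = FALSE] > expr[b, , drop = FALSE]) * 1
  rownames(pim) <- paste(a, b, sep = "|")
  pim
}

pair_label_genes <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  list(gene_a = vapply(parts, `[[`, "", 1L),
       gene_b = vapply(parts, `[[`, "", 2L))
}

#' Filter uninformative gene pairs
#'
#' Removes pairs whose indicator row has zero dispersion (absolute deviation
#' about the central value identically zero, i.e. the indicator is constant
#' across samples) OR whose minority value occurs in fewer than
#' `min_minor_frac` of the samples. The two criteria are applied
#' independently; surviving pair order is preserved and the operation is
#' idempotent. (A raw median-based MAD is not usable here: on a 0/1 row it
#' vanishes for every unbalanced row — and for every row when the sample
#' count is odd — so it would discard the entire candidate set.)
#'
#' @param pim pairs x samples 0/1 matrix from [build_pairs()].
#' @param min_minor_frac minimum minority-value fraction (default 0.20;
#'   removal when strictly below).
#' @return the filtered indicator matrix.
#' @export
filter_pairs <- function(pim, min_minor_frac = 0.20) {
  stopifnot(is.matrix(pim), ncol(pim) >= 1)
  assert_scalar_number(min_minor_frac, "min_minor_frac", 0, 0.5)
  p1 <- rowMeans(pim)
  minor <- pmin(p1, 1 - p1)
  dispersion <- apply(pim, 1, function(x) mean(abs(x - mean(x))))
  keep <- !(dispersion == 0 | minor < min_minor_frac)
  if (!any(keep)) {
    stop_pairsig("Every pair was filtered out; a larger or more heterogeneous cohort is needed.",
                 "pairsig_validation_error")
  }
  pim[keep, , drop = FALSE]
}

#' Score samples with a pair signature
#'
#' The risk score of a sample is the sum over signature pairs of
#' `coefficient * indicator`, with the indicator 1 exactly when
#' `expression(gene_a) > expression(gene_b)` in that sample.
#'
#' @param expr genes x samples matrix, or a named per-gene vector for a
#'   single sample.
#' @param signature a [pair_signature()].
#' @param allow_missing drop signature pairs whose genes are not measured
#'   (with a warning that the score scale changes) instead of erroring.
#' @return tibble (sample_id, score).
#' @export
risk_score <- function(expr, signature, allow_missing = FALSE) {
  stopifnot(inherits(signature, "pair_signature"))
  if (!is.matrix(expr)) {
    expr <- matrix(expr, ncol = 1, dimnames = list(names(expr), "sample"))
  }
  pairs <- signature$pairs
  missing <- setdiff(signature_genes(signature), rownames(expr))
  if (length(missing)) {
    if (!allow_missing) {
      stop_pairsig(paste0("Signature genes missing from expression: ",
                          paste(missing, collapse = ", ")),
                   "pairsig_validation_error")
    }
    drop <- pairs$gene_a %in% missing | pairs$gene_b %in% missing
    warn(sprintf("Dropping %d signature pair(s) with unmeasured genes; the score scale is no longer comparable to the full signature.",
                 sum(drop)))
    pairs <- pairs[!drop, , drop = FALSE]
    if (nrow(pairs) == 0) {
      stop_pairsig("No signature pair is measurable in this matrix.",
                   "pairsig_validation_error")
    }
  }
  ind <- (expr[pairs$gene_a, , drop = FALSE] >
            expr[pairs$gene_b, , drop = FALSE]) * 1
  tibble::tibble(sample_id = colnames(expr),
                 score = as.vector(crossprod(ind, pairs$coefficient)))
}

#' Classify samples into high and low risk
#'
#' Scores strictly above the cutoff are `"high"`, scores at or below it are
#' `"low"` (the boundary convention is the package's, documented rather than
#' inherited).
#'
#' @param scores numeric vector of risk scores (optionally named), or the
#'   tibble returned by [risk_score()].
#' @param cutoff finite risk-score cutoff.
#' @return character vector `"high"`/`"low"` (named when scores were named);
#'   when `scores` is a tibble, the tibble with a `group` column appended.
#' @export
classify_risk <- function(scores, cutoff) {
  assert_scalar_number(cutoff, "cutoff")
  if (is.data.frame(scores)) {
    scores$group <- ifelse(scores$score > cutoff, "high", "low")
    return(scores)
  }
  out <- ifelse(scores > cutoff, "high", "low")
  names(out) <- names(scores)
  out
}
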