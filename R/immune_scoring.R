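#' Single-sample gene-set enrichment score
#'
#' Rank-based single-sample enrichment in the ssGSEA style: genes are ranked
#' by expression (average rank for ties, higher expression = higher rank) and
#' the score is the sum over all rank positions, walked from the top of the
#' ranking down, of the difference between the weighted in-set empirical CDF
#' (weights `rank^alpha`, normalized within the set) and the unweighted
#' out-of-set empirical CDF. The score depends on the data only through ranks,
#' so it is invariant under any strictly increasing per-sample transform.
#'
#' @param sample_values named numeric vector, one expression value per gene.
#' @param gene_set character vector of member genes; must overlap the
#'   measured genes and be a strict subset of them.
#' @param alpha rank-weighting exponent (default 0.25, the ssGSEA convention).
#' @return a single numeric score.
#' @export
ssgsea_score <- function(sample_values, gene_set, alpha = 0.25) {
  if (is.null(names(sample_values))) {
    stop_pairsig("`sample_values` must be named by gene.",
                 "pairsig_validation_error")
  }
  assert_scalar_number(alpha, "alpha", lower = 0)
  gene_set <- unique(gene_set)
  in_set <- names(sample_values) %in% gene_set
  if (!any(in_set)) {
    missing <- setdiff(gene_set, names(sample_values))
    stop_pairsig(paste0("Gene set has no overlap with measured genes; missing: ",
                        paste(head(missing, 10), collapse = ", ")),
                 "pairsig_validation_error")
  }
  if (all(in_set)) {
    stop_pairsig("Gene set covers every measured gene; the out-of-set ECDF is undefined.",
                 "pairsig_validation_error")
  }
  n <- length(sample_values)
  r <- rank(sample_values, ties.method = "average")  # high expression = high rank
  # deterministic walk: decreasing value, gene name breaks ties
  ord <- order(-sample_values, names(sample_values))
  r_ord <- r[ord]
  in_ord <- in_set[ord]
  w <- ifelse(in_ord, r_ord^alpha, 0)
  ecdf_in <- cumsum(w) / sum(w)
  ecdf_out <- cumsum(!in_ord) / (n - sum(in_set))
  sum(ecdf_in - ecdf_out)
}

#' Stromal, immune and combined infiltration scores per sample
#'
#' Scores every sample against a stromal and an immune gene set with
#' [ssgsea_score()]; the combined (ESTIMATE-style) score is their sum. Scores
#' are raw single-sample enrichment sums, not normalized across samples; a
#' min-max rescaling is available for plotting only.
#'
#' @param expr genes x samples matrix.
#' @param stromal_set,immune_set character vectors of gene symbols.
#' @param alpha rank-weighting exponent passed to [ssgsea_score()].
#' @param normalize min-max rescale each score column to `[0, 1]` (plotting
#'   convenience; never used by downstream statistics).
#' @return tibble (sample_id, stromal, immune, estimate), samples in input
#'   order; `estimate = stromal + immune` exactly.
#' @export
estimate_scores <- function(expr, stromal_set, immune_set, alpha = 0.25,
                            normalize = FALSE) {
  assert_expression_matrix(expr)
  stromal <- apply(expr, 2, ssgsea_score, gene_set = stromal_set, alpha = alpha)
  immune <- apply(expr, 2, ssgsea_score, gene_set = immune_set, alpha = alpha)
  out <- tibble::tibble(
    sample_id = colnames(expr),
    stromal = unname(stromal),
    immune = unname(immune),
    estimate = unname(stromal + immune))
  if (normalize) {
    rescale <- function(x) if (diff(range(x)) == 0) x * 0 else
      (x - min(x)) / diff(range(x))
    out$stromal <- rescale(out$stromal)
    out$immune <- rescale(out$immune)
    out$estimate <- rescale(out$estimate)
  }
  out
}
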