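#' Reference-based deconvolution of bulk expression (constrained least squares)
#'
#' Estimates per-sample cell-type fractions by non-negative least squares of
#' the mixture onto the columns of a cell-type signature matrix, with the
#' non-negative coefficients normalized to sum to one. This is a
#' constrained-least-squares surrogate for support-vector-regression
#' deconvolution engines: it satisfies the same output contract
#' (non-negative fractions on the unit simplex) and is exactly testable on
#' synthetic mixtures, but it does not reproduce any published engine's
#' weighting or permutation significance.
#'
#' @param mixture genes x samples bulk matrix.
#' @param signature_matrix genes x cell-types reference profile matrix
#'   (full column rank; >= 2 cell types).
#' @return tibble (sample_id, one fraction column per cell type, residual);
#'   fraction columns are non-negative and each row sums to 1.
#' @export
deconvolve <- function(mixture, signature_matrix) {
  stopifnot(is.matrix(signature_matrix))
  if (ncol(signature_matrix) < 2) {
    stop_pairsig("Need at least 2 cell types in the signature matrix.",
                 "pairsig_validation_error")
  }
  shared <- intersect(rownames(signature_matrix), rownames(mixture))
  if (length(shared) < ncol(signature_matrix)) {
    stop_pairsig("Too few signature genes measured in the mixture.",
                 "pairsig_validation_error")
  }
  s <- signature_matrix[shared, , drop = FALSE]
  if (qr(s)$rank < ncol(s)) {
    stop_pairsig("Signature matrix is rank-deficient on the shared genes.",
                 "pairsig_validation_error")
  }
  m <- mixture[shared, , drop = FALSE]
  rows <- lapply(seq_len(ncol(m)), function(j) {
    sol <- pracma::lsqnonneg(s, m[, j])
    x <- sol$x
    frac <- if (sum(x) > 0) x / sum(x) else rep(1 / length(x), length(x))
    out <- tibble::as_tibble(as.list(setNames(frac, colnames(s))))
    out$residual <- sqrt(sum((m[, j] - s %*% x)^2))
    out
  })
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(m)),
                   dplyr::bind_rows(rows))
}

#' Wilcoxon rank-sum comparison of a feature between risk groups
#'
#' Exact-distribution p-value when the combined sample size is at most 25 and
#' the data are tie-free; otherwise the normal approximation with continuity
#' correction. `direction` reports which group has the larger median.
#'
#' @param values numeric feature per sample.
#' @param groups two-level group label per sample (e.g. `"high"`/`"low"`).
#' @return tibble (statistic, p_value, direction, n per group).
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2 || any(table(groups) == 0)) {
    stop_pairsig("`groups` must have exactly two non-empty levels.",
                 "pairsig_validation_error")
  }
  g1 <- levels(groups)[1]
  g2 <- levels(groups)[2]
  x <- values[groups == g1]
  y <- values[groups == g2]
  if (length(unique(c(x, y))) == 1) {
    warn("All values tied across both groups; p = 1.")
    return(tibble::tibble(statistic = length(x) * length(y) / 2, p_value = 1,
                          direction = "none", n_1 = length(x),
                          n_2 = length(y)))
  }
  n_total <- length(x) + length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- n_total <= 25 && !has_ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  med_diff <- median(x) - median(y)
  tibble::tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    direction = dplyr::case_when(med_diff > 0 ~ paste0("higher_in_", g1),
                                 med_diff < 0 ~ paste0("higher_in_", g2),
                                 TRUE ~ "none"),
    n_1 = length(x), n_2 = length(y))
}

#' Hub genes by degree in a candidate-induced interaction subgraph
#'
#' Restricts an undirected edge list to the candidate genes, deduplicates
#' edges and drops self-loops, and returns the candidates whose degree within
#' the induced subgraph is at least `min_degree`, sorted by degree descending
#' then gene name.
#'
#' @param edges data frame with columns `from`, `to`.
#' @param candidates character vector of candidate genes.
#' @param min_degree minimum degree (default 5, inclusive).
#' @return tibble (gene, degree); possibly empty.
#' @export
hub_genes <- function(edges, candidates, min_degree = 5) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  e <- edges[edges$from %in% candidates & edges$to %in% candidates &
               edges$from != edges$to, , drop = FALSE]
  if (nrow(e) == 0) {
    return(tibble::tibble(gene = character(), degree = integer()))
  }
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(g)
  out <- tibble::tibble(gene = names(deg), degree = as.integer(deg))
  out <- out[out$degree >= min_degree, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$gene)
}

#' Correlate gene expression with drug response across cell lines
#'
#' Pairwise Pearson correlation between every gene's cell-line expression and
#' every drug's IC50 over the shared cell lines (at least 3 required per
#' pair), with the two-sided t-test p-value; rows sorted by `|r|` descending.
#' Constant vectors are skipped with a warning.
#'
#' @param expr_cell_lines genes x cell-lines expression matrix.
#' @param ic50 drugs x cell-lines response matrix.
#' @return tibble (gene, drug, n, r, p_value).
#' @export
drug_correlation <- function(expr_cell_lines, ic50) {
  shared <- intersect(colnames(expr_cell_lines), colnames(ic50))
  n_skipped <- 0L
  rows <- list()
  for (g in rownames(expr_cell_lines)) {
    for (d in rownames(ic50)) {
      x <- expr_cell_lines[g, shared]
      y <- ic50[d, shared]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3) next
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      ct <- cor.test(x[ok], y[ok])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = g, drug = d, n = sum(ok), r = unname(ct$estimate),
        p_value = ct$p.value)
    }
  }
  if (n_skipped > 0) {
    warn(sprintf("%d gene-drug pair(s) skipped (constant vector).", n_skipped))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(gene = character(), drug = character(),
                          n = integer(), r = numeric(), p_value = numeric()))
  }
  dplyr::arrange(out, dplyr::desc(abs(.data$r)))
}
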