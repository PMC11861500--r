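wgcna_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue")

gene_cor_matrix <- function(expr) {
  assert_expression_matrix(expr)
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    stop_pairsig(paste0("Constant (zero-variance) gene(s): ",
                        paste(head(rownames(expr)[sds == 0], 5), collapse = ", ")),
                 "pairsig_validation_error")
  }
  cc <- cor(t(expr))
  if (any(!is.finite(cc))) {
    stop_pairsig("Non-finite gene-gene correlation encountered.",
                 "pairsig_validation_error")
  }
  cc
}

scale_free_fit <- function(k, n_bins = 10) {
  # frequency of binned connectivity vs mean connectivity per bin on
  # logarithmic bins (empty bins dropped), log-log regression; signed R^2
  # (negative slope = scale-free-like topology scores positive)
  kpos <- k[k > 0]
  if (length(unique(kpos)) < 3) return(list(r_squared = 0, slope = NA_real_))
  breaks <- 10^seq(log10(min(kpos)), log10(max(kpos)), length.out = n_bins + 1)
  breaks <- unique(breaks)
  if (length(breaks) < 3) return(list(r_squared = 0, slope = NA_real_))
  k <- kpos
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  ok <- is.finite(dk) & dk > 0 & pk > 0
  if (sum(ok) < 3) return(list(r_squared = 0, slope = NA_real_))
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  slope <- coef(fit)[2]
  list(r_squared = unname(-sign(slope) * r2), slope = unname(slope))
}

#' Choose the soft-threshold power for a co-expression network
#'
#' For each candidate power `beta` the unsigned adjacency
#' `a_ij = |cor(x_i, x_j)|^beta` is formed, per-gene connectivity
#' `k_i = sum_j a_ij` computed, and the scale-free topology fit measured as
#' the signed R^2 of the log-log regression of binned connectivity frequency
#' on mean binned connectivity (10 logarithmic bins, empty bins dropped).
#' The smallest power reaching `target_r2` is chosen; if none reaches it the
#' power with the maximum fit is returned with a warning.
#'
#' @param expr genes x samples matrix (at least 30 genes, 15 samples).
#' @param candidate_betas integer powers to scan.
#' @param target_r2 required scale-free fit (default 0.85).
#' @param n_bins connectivity histogram bins for the fit.
#' @return object of class `soft_threshold_fit`: list with `beta`,
#'   `r_squared`, `mean_connectivity` and a per-candidate `fit_table` tibble.
#' @export
pick_soft_threshold <- function(expr, candidate_betas = 1:20,
                                target_r2 = 0.85, n_bins = 10) {
  if (nrow(expr) < 30 || ncol(expr) < 15) {
    stop_pairsig("Soft-threshold selection needs >= 30 genes and >= 15 samples.",
                 "pairsig_validation_error")
  }
  cc <- abs(gene_cor_matrix(expr))
  diag(cc) <- 0
  rows <- lapply(candidate_betas, function(b) {
    a <- cc^b
    k <- rowSums(a)
    fit <- scale_free_fit(k, n_bins)
    tibble::tibble(beta = b, r_squared = fit$r_squared,
                   slope = fit$slope, mean_connectivity = mean(k))
  })
  tab <- dplyr::bind_rows(rows)
  hit <- which(tab$r_squared >= target_r2)
  if (length(hit)) {
    chosen <- hit[1]
  } else {
    chosen <- which.max(tab$r_squared)
    warn(sprintf("No candidate power reached scale-free R^2 >= %.2f; returning beta = %d (R^2 = %.3f).",
                 target_r2, tab$beta[chosen], tab$r_squared[chosen]))
  }
  structure(list(beta = tab$beta[chosen],
                 r_squared = tab$r_squared[chosen],
                 mean_connectivity = tab$mean_connectivity[chosen],
                 fit_table = tab),
            class = "soft_threshold_fit")
}

#' @export
print.soft_threshold_fit <- function(x, ...) {
  cat(sprintf("<soft_threshold_fit> beta = %d, scale-free R^2 = %.3f, mean connectivity = %.2f\n",
              x$beta, x$r_squared, x$mean_connectivity))
  invisible(x)
}

#' Topological overlap matrix
#'
#' Transforms the unsigned soft-thresholded adjacency into the topological
#' overlap similarity
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`, where `k` is connectivity. Entries lie in `[0, 1]`; two
#' genes overlap strongly when they are directly connected and share
#' neighbors.
#'
#' @param expr genes x samples matrix.
#' @param beta soft-threshold power (>= 1).
#' @return symmetric TOM matrix with gene dimnames.
#' @export
topological_overlap <- function(expr, beta) {
  assert_scalar_number(beta, "beta", lower = 1)
  a <- abs(gene_cor_matrix(expr))^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a         # diag(a)=0 makes u = i, j terms vanish
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the topological overlap
#' dissimilarity `1 - TOM`, cut statically at `cut_height`. Clusters smaller
#' than `min_module_size` are left unassigned (`"grey"`); the remaining
#' clusters receive color labels in decreasing size order from the
#' conventional palette starting `"turquoise"`.
#'
#' @param tom topological overlap matrix from [topological_overlap()].
#' @param min_module_size smallest cluster kept as a module (>= 3).
#' @param cut_height static cut height on the dendrogram.
#' @return tibble (gene, module).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  if (min_module_size < 3) {
    stop_pairsig("`min_module_size` must be at least 3.",
                 "pairsig_validation_error")
  }
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  d <- stats::as.dist(1 - tom)
  hc <- hclust(d, method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- sort(table(raw), decreasing = TRUE)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(raw))
  palette <- c(wgcna_colors, sprintf("module%02d", seq_len(max(0, length(big) - length(wgcna_colors)))))
  for (i in seq_along(big)) {
    labels[raw == as.integer(big[i])] <- palette[i]
  }
  tibble::tibble(gene = rownames(tom), module = labels)
}

module_eigengene <- function(expr_sub) {
  # first principal component of the standardized gene x sample submatrix,
  # unit norm, sign fixed so mean correlation with member genes is >= 0
  z <- t(scale(t(expr_sub)))
  sv <- svd(z, nu = 0, nv = 1)
  eig <- sv$v[, 1]
  eig <- eig / sqrt(sum(eig^2))
  cors <- cor(eig, t(expr_sub))
  if (mean(cors) < 0) eig <- -eig
  setNames(eig, colnames(expr_sub))
}

#' Module eigengenes and module-trait statistics
#'
#' Completes a module assignment: per module, the eigengene (first principal
#' component of the module's standardized expression submatrix, unit norm,
#' sign fixed so its mean correlation with member genes is non-negative);
#' module-trait Pearson correlations with two-sided t-test p-values; and
#' per-gene gene significance `GS = |cor(gene, trait)|` and module
#' membership `MM = |cor(gene, eigengene of its module)|`.
#'
#' @param expr genes x samples matrix.
#' @param modules tibble (gene, module) from [detect_modules()].
#' @param traits data frame with `sample_id` plus numeric trait columns,
#'   e.g. the output of [estimate_scores()].
#' @return object of class `module_assignment`: list with `modules` (tibble:
#'   gene, module, MM, one `GS_<trait>` column per trait), `eigengenes`
#'   (samples x modules matrix), `module_trait` (tibble: module, trait, r, p,
#'   n_genes).
#' @export
module_trait_statistics <- function(expr, modules, traits) {
  assert_expression_matrix(expr)
  stopifnot(all(c("gene", "module") %in% names(modules)))
  if (!"sample_id" %in% names(traits)) {
    stop_pairsig("`traits` must contain a `sample_id` column.",
                 "pairsig_validation_error")
  }
  traits <- traits[match(colnames(expr), traits$sample_id), , drop = FALSE]
  if (anyNA(traits$sample_id)) {
    stop_pairsig("`traits` does not cover every expression sample.",
                 "pairsig_validation_error")
  }
  trait_names <- setdiff(names(traits), "sample_id")
  for (tn in trait_names) {
    if (sd(traits[[tn]]) == 0) {
      stop_pairsig(sprintf("Trait '%s' is constant across samples; correlation undefined.", tn),
                   "pairsig_validation_error")
    }
  }
  modules <- modules[match(rownames(expr), modules$gene), ]
  mods <- setdiff(unique(modules$module), "grey")
  eig <- sapply(mods, function(m) {
    module_eigengene(expr[modules$module == m, , drop = FALSE])
  })
  if (length(mods) == 1) eig <- matrix(eig, ncol = 1, dimnames = list(colnames(expr), mods))

  mt <- tidyr::expand_grid(module = mods, trait = trait_names)
  mt <- dplyr::mutate(mt, r = NA_real_, p = NA_real_, n_genes = NA_integer_)
  for (i in seq_len(nrow(mt))) {
    ct <- cor.test(eig[, mt$module[i]], traits[[mt$trait[i]]])
    mt$r[i] <- unname(ct$estimate)
    mt$p[i] <- ct$p.value
    mt$n_genes[i] <- sum(modules$module == mt$module[i])
  }

  mm <- rep(NA_real_, nrow(expr))
  for (m in mods) {
    idx <- which(modules$module == m)
    mm[idx] <- abs(cor(t(expr[idx, , drop = FALSE]), eig[, m]))[, 1]
  }
  gene_tab <- tibble::tibble(gene = rownames(expr), module = modules$module,
                             MM = mm)
  for (tn in trait_names) {
    gene_tab[[paste0("GS_", tn)]] <-
      abs(as.vector(cor(t(expr), traits[[tn]])))
  }

  structure(list(modules = gene_tab, eigengenes = eig, module_trait = mt),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d genes, %d modules (+grey)\n",
              nrow(x$modules), ncol(x$eigengenes)))
  print(x$module_trait, ...)
  invisible(x)
}

#' @export
tidy.module_assignment <- function(x, ...) x$module_trait

#' @export
glance.module_assignment <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$modules),
                 n_modules = ncol(x$eigengenes),
                 n_grey = sum(x$modules$module == "grey"))
}

#' Select the immune-related module and return its genes
#'
#' A module qualifies when the absolute correlation of its eigengene with the
#' selection trait (default the combined `estimate` score) exceeds `r_min`
#' with `p < p_max`. When several qualify, the module with the largest
#' immune-score correlation wins. Returns the member genes in stable (input)
#' order; an empty vector with a warning when no module qualifies.
#'
#' @param assignment a [module_trait_statistics()] result.
#' @param trait trait used for the qualification threshold.
#' @param r_min minimum absolute module-trait correlation.
#' @param p_max maximum module-trait p-value.
#' @param selection_trait trait used to rank qualifying modules.
#' @return character vector of gene symbols (the immune-related genes).
#' @export
select_immune_module <- function(assignment, trait = "estimate", r_min = 0.6,
                                 p_max = 0.05, selection_trait = "immune") {
  stopifnot(inherits(assignment, "module_assignment"))
  mt <- assignment$module_trait
  qual <- mt[mt$trait == trait & abs(mt$r) > r_min & mt$p < p_max, ]
  if (nrow(qual) == 0) {
    warn(sprintf("No module passed |r| > %.2f and p < %.2g on trait '%s'.",
                 r_min, p_max, trait))
    return(character())
  }
  sel <- mt[mt$trait == selection_trait & mt$module %in% qual$module, ]
  if (nrow(sel) == 0) sel <- qual
  winner <- sel$module[which.max(sel$r)]
  assignment$modules$gene[assignment$modules$module == winner]
}
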