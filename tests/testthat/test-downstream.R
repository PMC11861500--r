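sig_matrix_fixture <- function(seed = 50) {
  set.seed(seed)
  sig <- matrix(runif(30 * 3, 0.5, 2), 30, 3,
                dimnames = list(sprintf("m%02d", 1:30),
                                c("T_cell", "B_cell", "Fibro")))
  for (j in 1:3) sig[((j - 1) * 10 + 1):(j * 10), j] <- runif(10, 8, 12)
  sig
}

test_that("deconvolution recovers exact mixtures and keeps the simplex", {
  sig <- sig_matrix_fixture()
  # pure column
  pure <- matrix(sig[, "T_cell"], ncol = 1,
                 dimnames = list(rownames(sig), "pure"))
  fr <- deconvolve(pure, sig)
  expect_equal(fr$T_cell, 1, tolerance = 1e-9)
  expect_equal(fr$B_cell + fr$Fibro, 0, tolerance = 1e-9)

  # noiseless 0.5/0.3/0.2 mixture
  mix <- matrix(sig %*% c(0.5, 0.3, 0.2), ncol = 1,
                dimnames = list(rownames(sig), "mix"))
  fr2 <- deconvolve(mix, sig)
  expect_equal(unlist(fr2[, colnames(sig)]), c(T_cell = 0.5, B_cell = 0.3,
                                               Fibro = 0.2), tolerance = 1e-6)
  expect_equal(fr2$residual, 0, tolerance = 1e-8)

  # a mixture containing an unmodeled component still yields simplex fractions
  set.seed(51)
  alien <- matrix(sig %*% c(0.6, 0.4, 0) + runif(30, 0, 5), ncol = 1,
                  dimnames = list(rownames(sig), "alien"))
  fr3 <- deconvolve(alien, sig)
  vals <- unlist(fr3[, colnames(sig)])
  expect_true(all(vals >= 0))
  expect_equal(sum(vals), 1, tolerance = 1e-9)
  expect_gt(fr3$residual, 0)

  rankdef <- cbind(sig, dup = sig[, 1])
  expect_error(deconvolve(mix, rankdef), "rank-deficient")
  expect_error(deconvolve(mix, sig[, 1, drop = FALSE]), "2 cell types")
})

test_that("rank-sum comparisons match exhaustive enumeration and flip with labels", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  vals <- c(x, y)
  grp <- rep(c("high", "low"), each = 3)
  got <- compare_groups(vals, grp)
  expect_equal(got$p_value, oracle_wilcox_exact(x, y))
  expect_equal(got$p_value, 0.1)  # 2 extreme arrangements of choose(6,3)=20

  # label swap preserves p and flips direction
  swapped <- compare_groups(vals, rev(grp))
  expect_equal(swapped$p_value, got$p_value)
  expect_equal(got$direction, "higher_in_low")
  expect_equal(swapped$direction, "higher_in_high")

  # a second uneven fixture against the enumeration oracle
  x2 <- c(0.3, 2.2, 9.1, 4.4); y2 <- c(1.1, 0.2)
  got2 <- compare_groups(c(x2, y2), rep(c("a", "b"), c(4, 2)))
  expect_equal(got2$p_value, oracle_wilcox_exact(x2, y2))

  expect_warning(tied <- compare_groups(rep(1, 6), grp), "tied")
  expect_equal(tied$p_value, 1)
  expect_error(compare_groups(vals, rep("high", 6)), "two non-empty")
})

test_that("rank-sum power is high for a one-sd shift at n = 50 per group", {
  set.seed(52)
  hits <- vapply(1:500, function(r) {
    v <- c(rnorm(50, 1), rnorm(50, 0))
    compare_groups(v, rep(c("h", "l"), each = 50))$p_value < 0.05
  }, NA)
  expect_gt(mean(hits), 0.9)
})

test_that("hub genes are degree-filtered on the candidate-induced subgraph", {
  star <- tibble::tibble(from = rep("HUB", 6),
                         to = paste0("L", 1:6))
  cands <- c("HUB", paste0("L", 1:6))
  hubs <- hub_genes(star, cands, min_degree = 5)
  expect_equal(hubs$gene, "HUB")
  expect_equal(hubs$degree, 6L)

  # degree exactly 5 is included; non-candidate edges are ignored
  five <- tibble::tibble(from = c(rep("A", 5), "A", "A"),
                         to = c(paste0("B", 1:5), "OUT1", "A"))
  got <- hub_genes(five, c("A", paste0("B", 1:5)), min_degree = 5)
  expect_equal(got$gene, "A")
  expect_equal(got$degree, 5L)

  # order-independence and duplicate-edge tolerance
  shuffled <- five[sample(nrow(five)), ]
  doubled <- dplyr::bind_rows(five, five)
  expect_equal(hub_genes(shuffled, c("A", paste0("B", 1:5))), got)
  expect_equal(hub_genes(doubled, c("A", paste0("B", 1:5))), got)

  expect_equal(nrow(hub_genes(star, c("L1", "L2"))), 0)
})

test_that("gene-drug correlations behave at both extremes", {
  set.seed(53)
  lines <- sprintf("CL%02d", 1:60)
  expr <- matrix(rnorm(2 * 60, 6), 2, 60,
                 dimnames = list(c("GENE1", "GENE2"), lines))
  ic50 <- matrix(rnorm(2 * 60), 2, 60,
                 dimnames = list(c("affine", "noise"), lines))
  ic50["affine", ] <- 3 - 2 * expr["GENE1", ]
  out <- drug_correlation(expr, ic50)
  top <- out[out$gene == "GENE1" & out$drug == "affine", ]
  expect_equal(top$r, -1, tolerance = 1e-12)
  expect_lt(top$p_value, 1e-12)
  expect_equal(out$gene[1], "GENE1")  # sorted by |r|

  # null distribution of |r| at n = 60 over 1000 independent pairs
  set.seed(54)
  null_expr <- matrix(rnorm(25 * 60), 25, 60,
                      dimnames = list(sprintf("g%02d", 1:25), lines))
  null_ic <- matrix(rnorm(40 * 60), 40, 60,
                    dimnames = list(sprintf("d%02d", 1:40), lines))
  nn <- drug_correlation(null_expr, null_ic)
  expect_equal(nrow(nn), 1000)
  expect_lt(quantile(abs(nn$r), 0.95), 0.26)

  # fewer than 3 shared lines: the pair is absent
  tiny_ic <- matrix(rnorm(2), 1, 2,
                    dimnames = list("d", lines[1:2]))
  expect_equal(nrow(drug_correlation(expr, tiny_ic)), 0)
  # constant vectors are skipped with a warning
  const_ic <- matrix(1, 1, 60, dimnames = list("const", lines))
  expect_warning( skipped <- drug_correlation(expr, const_ic), "skipped")
  expect_equal(nrow(skipped), 0)
})
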