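make_block_expr <- function(n_blocks = 2, block_size = 50, n_samples = 60,
                            within = 0.9, seed = 8, noise_genes = 0) {
  set.seed(seed)
  p <- n_blocks * block_size + noise_genes
  factors <- matrix(rnorm(n_blocks * n_samples), n_blocks, n_samples)
  m <- matrix(rnorm(p * n_samples, sd = sqrt(1 - within)), p, n_samples)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    m[idx, ] <- m[idx, ] + sqrt(within) * rep(1, block_size) %o% factors[b, ]
  }
  rownames(m) <- sprintf("G%03d", seq_len(p))
  colnames(m) <- sprintf("S%03d", seq_len(n_samples))
  list(expr = m, block = rep(c(seq_len(n_blocks), 0),
                             c(rep(block_size, n_blocks), noise_genes)),
       factors = factors)
}

test_that("TOM matches an explicit triple-loop evaluation and its contract", {
  set.seed(9)
  expr <- toy_expr(matrix(rnorm(4 * 30, 5), 4, 30))
  beta <- 3
  adj <- abs(cor(t(expr)))^beta
  diag(adj) <- 0
  tom <- topological_overlap(expr, beta)
  expect_equal(unname(tom), oracle_tom(adj), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom, t(tom))

  # identical expression vectors give adjacency 1 and (in the two-gene
  # network, where no third neighbor dilutes the overlap) TOM exactly 1
  expr2 <- expr[1:2, ]
  expr2[2, ] <- expr2[1, ]
  tom2 <- topological_overlap(expr2, beta)
  expect_equal(unname(tom2[1, 2]), 1, tolerance = 1e-12)

  const <- expr
  const[3, ] <- 2
  expect_error(topological_overlap(const, beta), "G03")
})

test_that("adjacency and TOM are invariant under per-gene affine rescaling", {
  set.seed(10)
  expr <- toy_expr(matrix(rnorm(20 * 40, 6), 20, 40))
  scaled <- expr * runif(20, 0.5, 3) + runif(20, -5, 5)
  expect_equal(topological_overlap(expr, 4), topological_overlap(scaled, 4),
               tolerance = 1e-10)
})

test_that("scale-free fit scores an exact power-law degree sequence near 1", {
  # frequency of connectivity k proportional to k^-2, by construction
  kvals <- 2^(1:8)
  counts <- round(1e5 * kvals^-2)
  k <- rep(kvals, counts)
  fit <- pairsig:::scale_free_fit(k, n_bins = 10)
  expect_gte(fit$r_squared, 0.99)
  expect_lt(fit$slope, 0)
})

test_that("soft-threshold selection picks the smallest qualifying power", {
  blocks <- make_block_expr(n_blocks = 3, block_size = 20, n_samples = 50,
                            within = 0.85, seed = 11)
  fit <- pick_soft_threshold(blocks$expr, candidate_betas = 1:12,
                             target_r2 = 0.5)
  tab <- fit$fit_table
  qualifying <- tab$beta[tab$r_squared >= 0.5]
  if (length(qualifying)) {
    expect_equal(fit$beta, min(qualifying))
  }
  # unreachable target falls back to the maximum with a warning
  expect_warning(
    fb <- pick_soft_threshold(blocks$expr, candidate_betas = 1:3,
                              target_r2 = 0.999),
    "No candidate power")
  expect_equal(fb$r_squared, max(fb$fit_table$r_squared))
  expect_error(pick_soft_threshold(blocks$expr[1:10, ]), "30 genes")
})

test_that("planted correlation blocks are recovered as modules", {
  for (seed in c(21, 22, 23)) {
    blocks <- make_block_expr(n_blocks = 2, block_size = 50, n_samples = 80,
                              within = 0.9, seed = seed)
    tom <- topological_overlap(blocks$expr, 6)
    mods <- detect_modules(tom, min_module_size = 30, cut_height = 0.995)
    non_grey <- setdiff(unique(mods$module), "grey")
    expect_equal(length(non_grey), 2)
    # label agreement: every block maps to one dominant module
    for (b in 1:2) {
      in_block <- mods$module[blocks$block == b]
      expect_gte(max(table(in_block)) / length(in_block), 0.98)
    }
  }
})

test_that("uncorrelated genes go grey and identical genes form one module", {
  set.seed(12)
  noise <- toy_expr(matrix(rnorm(50 * 60), 50, 60))
  tom <- topological_overlap(noise, 6)
  mods <- detect_modules(tom, min_module_size = 30, cut_height = 0.5)
  expect_true(all(mods$module == "grey"))

  # all genes mutually identical: TOM of ones clusters everything together
  tom1 <- matrix(1, 40, 40, dimnames = list(sprintf("G%02d", 1:40),
                                            sprintf("G%02d", 1:40)))
  mods1 <- detect_modules(tom1, min_module_size = 30, cut_height = 0.99)
  expect_equal(unique(mods1$module), "turquoise")
  expect_error(detect_modules(tom1, min_module_size = 2), "at least 3")
})

test_that("module-trait statistics behave like correlations should", {
  blocks <- make_block_expr(n_blocks = 2, block_size = 40, n_samples = 100,
                            within = 0.9, seed = 13)
  tom <- topological_overlap(blocks$expr, 6)
  mods <- detect_modules(tom, min_module_size = 30, cut_height = 0.995)
  lead <- setdiff(unique(mods$module), "grey")[1]

  # trait equal to an eigengene correlates at r = 1 with that module
  pre <- module_trait_statistics(
    blocks$expr, mods,
    tibble::tibble(sample_id = colnames(blocks$expr),
                   estimate = rnorm(100)))
  eig <- pre$eigengenes[, lead]
  traits <- tibble::tibble(sample_id = colnames(blocks$expr),
                           estimate = eig, immune = rnorm(100))
  asg <- module_trait_statistics(blocks$expr, mods, traits)
  row <- asg$module_trait[asg$module_trait$module == lead &
                           asg$module_trait$trait == "estimate", ]
  expect_equal(row$r, 1, tolerance = 1e-8)
  expect_lt(row$p, 1e-12)

  # permuted traits give correlations concentrated near zero
  set.seed(14)
  perms <- replicate(200, {
    tr <- tibble::tibble(sample_id = colnames(blocks$expr),
                         estimate = sample(eig))
    a <- module_trait_statistics(blocks$expr, mods, tr)
    abs(a$module_trait$r[a$module_trait$module == lead])
  })
  expect_lt(quantile(perms, 0.95), 0.4)

  # eigengene of a one-gene module is that gene's standardized expression
  one <- tibble::tibble(gene = rownames(blocks$expr),
                        module = c("solo", rep("grey", 79)))
  a1 <- module_trait_statistics(blocks$expr, one, traits)
  g <- scale(blocks$expr[1, ])[, 1]
  e1 <- a1$eigengenes[, "solo"]
  expect_equal(abs(cor(e1, g)), 1, tolerance = 1e-10)
  expect_gte(cor(e1, blocks$expr[1, ]), 0)  # sign convention

  const_trait <- tibble::tibble(sample_id = colnames(blocks$expr),
                                estimate = 1)
  expect_error(module_trait_statistics(blocks$expr, mods, const_trait),
               "estimate")
})

test_that("immune-module selection applies thresholds and prefers the stronger module", {
  fake <- structure(list(
    modules = tibble::tibble(gene = sprintf("G%02d", 1:40),
                             module = rep(c("turquoise", "blue"), each = 20)),
    eigengenes = matrix(0, 2, 2,
                        dimnames = list(NULL, c("turquoise", "blue"))),
    module_trait = tibble::tibble(
      module = rep(c("turquoise", "blue"), each = 2),
      trait = rep(c("estimate", "immune"), 2),
      r = c(0.7, 0.7, 0.8, 0.9),
      p = c(1e-4, 1e-4, 1e-4, 1e-4),
      n_genes = 20L)), class = "module_assignment")
  expect_equal(select_immune_module(fake), sprintf("G%02d", 21:40))
  # and respects the qualification thresholds
  fake$module_trait$r <- c(0.5, 0.9, 0.55, 0.9)
  expect_warning(out <- select_immune_module(fake), "No module")
  expect_length(out, 0)
})
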