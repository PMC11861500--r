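#' Specify a synthetic tumor expression cohort
#'
#' Collects every parameter of the synthetic cohort generator into a validated
#' spec. The generator emulates the structure of a bulk tumor cohort with
#' (a) a binary driver-mutation label carrying differentially expressed genes,
#' (b) a latent immune-infiltration factor loading on a correlated gene block,
#' and (c) right-censored overall survival from a proportional-hazards model
#' whose linear predictor is a weighted sum of relative-rank gene-pair
#' indicators plus (optionally) the immune factor.
#'
#' Gene symbols are generated as `sprintf("g%04d", 1:n_genes)`. The immune
#' block occupies the first `n_immune_block` genes and the mutation-responsive
#' (DE) genes the first `n_de_genes`, so the immune block is nested inside the
#' DE set whenever `n_de_genes >= n_immune_block` — mirroring a pipeline in
#' which immune-related genes are screened from among the DE genes.
#'
#' @param n_samples number of tumor samples.
#' @param n_genes number of genes.
#' @param n_immune_block number of genes loaded on the latent immune factor.
#' @param mutation_fraction fraction of samples carrying the driver mutation
#'   (default 44/504, the mutant/wild-type split of the cohort the generator
#'   emulates).
#' @param n_de_genes number of genes shifted between mutant and wild-type.
#' @param de_effect log2-scale mean shift applied to DE genes in mutants.
#' @param prop_up fraction of DE genes shifted upward in mutants.
#' @param immune_loading_range range (length-2) of per-gene loadings on the
#'   latent immune factor. The default (1.5-2.5 over unit noise) gives
#'   module-membership correlations near 0.9, the strength reported for
#'   immune-infiltration modules in bulk tumor cohorts.
#' @param true_pairs data frame with columns `gene_a`, `gene_b`, `weight`:
#'   gene pairs whose rank indicators enter the survival linear predictor.
#' @param immune_hazard coefficient of the latent immune factor in the
#'   survival linear predictor (0 = survival driven only by the pairs).
#' @param baseline_hazard baseline hazard, per year.
#' @param weibull_shape Weibull shape of the baseline (1 = exponential).
#' @param censor_rate target fraction of censored samples in `[0, 1)`.
#' @param noise_sd per-gene Gaussian noise standard deviation (log2 scale).
#' @param zero_prob probability a measured value is zeroed ("not detected").
#' @param seed integer seed; identical specs produce identical cohorts.
#' @return an object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_samples = 300, n_genes = 1000, n_immune_block = 100,
                        mutation_fraction = 44 / 504, n_de_genes = 300,
                        de_effect = 1, prop_up = 0.27,
                        immune_loading_range = c(1.5, 2.5),
                        true_pairs = NULL, immune_hazard = 0,
                        baseline_hazard = 0.15, weibull_shape = 1,
                        censor_rate = 0.3, noise_sd = 1, zero_prob = 0.02,
                        seed = 1L) {
  spec <- list(
    n_samples = n_samples, n_genes = n_genes, n_immune_block = n_immune_block,
    mutation_fraction = mutation_fraction, n_de_genes = n_de_genes,
    de_effect = de_effect, prop_up = prop_up,
    immune_loading_range = immune_loading_range,
    true_pairs = true_pairs, immune_hazard = immune_hazard,
    baseline_hazard = baseline_hazard, weibull_shape = weibull_shape,
    censor_rate = censor_rate, noise_sd = noise_sd, zero_prob = zero_prob,
    seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  assert_scalar_number(spec$n_samples, "n_samples", lower = 2)
  assert_scalar_number(spec$n_genes, "n_genes", lower = 2)
  assert_scalar_number(spec$n_immune_block, "n_immune_block", lower = 0,
                       upper = spec$n_genes)
  if (spec$n_de_genes > spec$n_genes) {
    stop_pairsig(sprintf(
      "`n_de_genes` (%d) exceeds `n_genes` (%d).",
      spec$n_de_genes, spec$n_genes), "pairsig_validation_error")
  }
  assert_scalar_number(spec$n_de_genes, "n_de_genes", lower = 0)
  assert_scalar_number(spec$mutation_fraction, "mutation_fraction",
                       lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(spec$de_effect, "de_effect")
  assert_scalar_number(spec$prop_up, "prop_up", lower = 0, upper = 1)
  if (length(spec$immune_loading_range) != 2L ||
      spec$immune_loading_range[1] > spec$immune_loading_range[2]) {
    stop_pairsig("`immune_loading_range` must be an increasing pair of reals.",
                 "pairsig_validation_error")
  }
  assert_scalar_number(spec$baseline_hazard, "baseline_hazard", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(spec$weibull_shape, "weibull_shape", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(spec$censor_rate, "censor_rate", lower = 0, upper = 1,
                       strict_upper = TRUE)
  assert_scalar_number(spec$noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  assert_scalar_number(spec$zero_prob, "zero_prob", lower = 0, upper = 1)
  assert_scalar_number(spec$immune_hazard, "immune_hazard")
  genes <- cohort_gene_names(spec$n_genes)
  if (!is.null(spec$true_pairs)) {
    tp <- spec$true_pairs
    if (!all(c("gene_a", "gene_b", "weight") %in% names(tp))) {
      stop_pairsig("`true_pairs` needs columns gene_a, gene_b, weight.",
                   "pairsig_validation_error")
    }
    unknown <- setdiff(c(tp$gene_a, tp$gene_b), genes)
    if (length(unknown)) {
      stop_pairsig(paste0("`true_pairs` names genes absent from the cohort: ",
                          paste(unknown, collapse = ", ")),
                   "pairsig_validation_error")
    }
    if (any(tp$gene_a == tp$gene_b)) {
      stop_pairsig("`true_pairs` contains self-pairs.", "pairsig_validation_error")
    }
  }
  invisible(spec)
}

cohort_gene_names <- function(n) sprintf("g%04d", seq_len(n))

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  force(code)
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Draws a gene-by-sample log2-scale expression matrix, a clinical table with
#' right-censored survival, and a truth record. Expression is
#' `baseline + loading * immune_factor (immune-block genes) +
#' direction * de_effect * mutation (DE genes) + noise`, zero-inflated with
#' probability `zero_prob` and clamped at zero so "not detected" arises
#' naturally. Event times follow a Weibull proportional-hazards model with
#' linear predictor `sum(weight_k * pair_indicator_k) +
#' immune_hazard * immune_factor`; censoring is an independent exponential
#' time whose rate is calibrated numerically so the realized censoring
#' fraction matches `censor_rate`.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `expression` (genes x samples matrix),
#'   `clinical` (tibble: sample_id, os_time in days, os_event, age, gender,
#'   tnm_stage, mutation) and `truth` (DE genes and directions, immune-block
#'   genes and loadings, latent factor, true pairs, linear predictor, latent
#'   event/censoring times in years).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  with_preserved_rng({
    set.seed(spec$seed)
    n <- spec$n_samples
    p <- spec$n_genes
    genes <- cohort_gene_names(p)
    samples <- sprintf("s%04d", seq_len(n))

    mutation <- integer(n)
    n_mut <- max(1L, round(spec$mutation_fraction * n))
    mutation[sample.int(n, n_mut)] <- 1L

    immune_factor <- rnorm(n)
    baseline <- runif(p, 4, 10)
    loading <- numeric(p)
    if (spec$n_immune_block > 0) {
      loading[seq_len(spec$n_immune_block)] <-
        runif(spec$n_immune_block, spec$immune_loading_range[1],
              spec$immune_loading_range[2])
    }
    de_dir <- numeric(p)
    if (spec$n_de_genes > 0) {
      idx <- seq_len(spec$n_de_genes)
      de_dir[idx] <- ifelse(runif(spec$n_de_genes) < spec$prop_up, 1, -1)
    }

    expr <- baseline +
      outer(loading, immune_factor) +
      spec$de_effect * outer(de_dir, mutation) +
      matrix(rnorm(p * n, sd = spec$noise_sd), p, n)
    if (spec$zero_prob > 0) {
      expr[matrix(runif(p * n) < spec$zero_prob, p, n)] <- 0
    }
    expr <- pmax(expr, 0)
    dimnames(expr) <- list(genes, samples)

    lp <- spec$immune_hazard * immune_factor
    tp <- spec$true_pairs
    if (!is.null(tp) && nrow(tp) > 0) {
      for (k in seq_len(nrow(tp))) {
        ind <- as.numeric(expr[tp$gene_a[k], ] > expr[tp$gene_b[k], ])
        lp <- lp + tp$weight[k] * ind
      }
    }

    # Weibull PH: S(t) = exp(-h0 * t^shape * exp(lp))
    e <- rexp(n)
    event_time <- (e / (spec$baseline_hazard * exp(lp)))^(1 / spec$weibull_shape)
    if (spec$censor_rate > 0) {
      theta <- uniroot(
        function(th) mean(1 - exp(-th * event_time)) - spec$censor_rate,
        lower = 1e-10, upper = 1e10, tol = 1e-12)$root
      censor_time <- rexp(n, rate = theta)
    } else {
      censor_time <- rep(Inf, n)
    }
    os_time_years <- pmin(event_time, censor_time)
    os_event <- as.integer(event_time <= censor_time)

    age <- round(pmin(90, pmax(40, rnorm(n, 67, 9))))
    gender <- ifelse(runif(n) < 0.74, "M", "F")
    # TNM correlated with the linear predictor: rank-bin lp + noise into the
    # cohort's marginal stage frequencies
    stage_score <- lp + rnorm(n)
    stage_breaks <- quantile(stage_score, c(0, 0.423, 0.707, 0.86, 1))
    tnm <- cut(stage_score, breaks = unique(stage_breaks),
               labels = c("I", "II", "III", "IV")[seq_len(length(unique(stage_breaks)) - 1)],
               include.lowest = TRUE, ordered_result = TRUE)

    clinical <- tibble::tibble(
      sample_id = samples,
      os_time = os_time_years * 365.25,
      os_event = os_event,
      age = as.numeric(age),
      gender = gender,
      tnm_stage = tnm,
      mutation = mutation)

    truth <- list(
      de_genes = genes[de_dir != 0],
      de_direction = de_dir[de_dir != 0],
      immune_block = genes[loading != 0],
      loadings = loading[loading != 0],
      immune_factor = setNames(immune_factor, samples),
      true_pairs = if (is.null(tp)) {
        tibble::tibble(gene_a = character(), gene_b = character(),
                       weight = numeric())
      } else tibble::as_tibble(tp),
      linear_predictor = setNames(lp, samples),
      event_time_years = setNames(event_time, samples),
      censor_time_years = setNames(censor_time, samples))

    list(expression = expr, clinical = clinical, truth = truth)
  })
}

#' Simulate downstream fixtures tied to a cohort spec
#'
#' Builds the auxiliary inputs the downstream stages consume: disjoint
#' "stromal" and "immune" gene sets carved out of the cohort's immune block, a
#' cell-type signature matrix with synthetic mixtures of known fractions, a
#' cell-line drug panel containing one drug constructed to correlate with a
#' named gene, and an interaction edge list containing a hub node.
#'
#' @param spec a [cohort_spec()]; its seed (offset by 1) drives all draws here.
#' @param n_cell_lines number of cell lines in the drug panel.
#' @param target_r target Pearson correlation between the constructed drug's
#'   IC50 and its target gene.
#' @return list with `gene_sets` (list of two disjoint character vectors),
#'   `signature_matrix` (marker genes x cell types), `mixture` (list: `values`
#'   marker genes x mixtures, `fractions` known mixing tibble), `drug_panel`
#'   (list: `expression`, `ic50`, `target_gene`, `target_drug`, `target_r`)
#'   and `edges` (two-column tibble with at least one node of degree >= 5).
#' @export
simulate_fixtures <- function(spec, n_cell_lines = 60, target_r = 0.9) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_immune_block < 4) {
    stop_pairsig("immune block too small to split into two disjoint gene sets (need n_immune_block >= 4).",
                 "pairsig_validation_error")
  }
  with_preserved_rng({
    set.seed(spec$seed + 1L)
    genes <- cohort_gene_names(spec$n_genes)
    block <- genes[seq_len(spec$n_immune_block)]
    half <- floor(length(block) / 2)
    gene_sets <- list(stromal = block[seq_len(half)],
                      immune = block[(half + 1):length(block)])

    cell_types <- c("T_cell", "B_cell", "Fibroblast")
    markers <- sprintf("m%03d", 1:60)
    sig <- matrix(runif(60 * 3, 0.5, 2), 60, 3,
                  dimnames = list(markers, cell_types))
    for (j in 1:3) sig[((j - 1) * 20 + 1):(j * 20), j] <- runif(20, 8, 12)

    n_mix <- 20
    fr <- matrix(rgamma(n_mix * 3, shape = 1), n_mix, 3)
    fr <- fr / rowSums(fr)
    colnames(fr) <- cell_types
    mix <- sig %*% t(fr)
    colnames(mix) <- sprintf("mix%02d", seq_len(n_mix))
    mixture <- list(
      values = mix,
      fractions = dplyr::bind_cols(
        tibble::tibble(sample_id = colnames(mix)), tibble::as_tibble(fr)))

    lines <- sprintf("CL%02d", seq_len(n_cell_lines))
    panel_genes <- block[seq_len(min(10, length(block)))]
    cl_expr <- matrix(rnorm(length(panel_genes) * n_cell_lines, 6, 1.5),
                      length(panel_genes), n_cell_lines,
                      dimnames = list(panel_genes, lines))
    target_gene <- panel_genes[1]
    z <- scale(cl_expr[target_gene, ])[, 1]
    drugs <- c("drug_target", "drug_null_a", "drug_null_b")
    ic50 <- matrix(rnorm(length(drugs) * n_cell_lines), length(drugs),
                   n_cell_lines, dimnames = list(drugs, lines))
    ic50["drug_target", ] <- target_r * z +
      sqrt(1 - target_r^2) * rnorm(n_cell_lines)

    hub <- block[1]
    spokes <- block[2:7]
    extra_a <- sample(genes, 6)
    extra_b <- sample(genes, 6)
    edges <- tibble::tibble(
      from = c(rep(hub, length(spokes)), extra_a),
      to = c(spokes, extra_b))
    edges <- dplyr::filter(edges, .data$from != .data$to)

    list(gene_sets = gene_sets, signature_matrix = sig, mixture = mixture,
         drug_panel = list(expression = cl_expr, ic50 = ic50,
                           target_gene = target_gene,
                           target_drug = "drug_target", target_r = target_r),
         edges = edges)
  })
}

#' Choose plantable gene pairs from a simulated cohort
#'
#' Identifies gene pairs whose relative-rank indicator varies enough to
#' survive the minority-fraction filter, for use as `true_pairs` in a second
#' simulation under the same seed. Because `true_pairs` affects only the
#' survival draw (never the expression draw), re-simulating the same spec
#' with the chosen pairs reproduces the identical expression matrix while
#' making survival depend on the planted indicators.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param n_pairs number of pairs to plant.
#' @param genes candidate genes (default: the cohort's immune block).
#' @param min_minor_frac required minority fraction of the indicator.
#' @param weights weights to attach (recycled), e.g. `c(-0.8, 0.8)`.
#' @return tibble (gene_a, gene_b, weight) usable as `true_pairs`; pairs are
#'   gene-disjoint so their indicators are not trivially collinear.
#' @export
choose_planted_pairs <- function(cohort, n_pairs,
                                 genes = cohort$truth$immune_block,
                                 min_minor_frac = 0.3,
                                 weights = c(-0.8, 0.8)) {
  pim <- build_pairs(cohort$expression, genes)
  p1 <- rowMeans(pim)
  ok <- pmin(p1, 1 - p1) >= min_minor_frac
  labels <- rownames(pim)[ok]
  lg <- pair_label_genes(labels)
  chosen <- integer(0)
  used <- character(0)
  for (i in seq_along(labels)) {
    if (length(chosen) == n_pairs) break
    if (lg$gene_a[i] %in% used || lg$gene_b[i] %in% used) next
    chosen <- c(chosen, i)
    used <- c(used, lg$gene_a[i], lg$gene_b[i])
  }
  if (length(chosen) < n_pairs) {
    stop_pairsig(sprintf("Only %d gene-disjoint variable pairs available; asked for %d.",
                         length(chosen), n_pairs), "pairsig_validation_error")
  }
  tibble::tibble(gene_a = lg$gene_a[chosen], gene_b = lg$gene_b[chosen],
                 weight = rep_len(weights, n_pairs))
}
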