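#' Assemble and validate a pipeline configuration
#'
#' Collects every tunable threshold of the end-to-end analysis in one place.
#' Defaults are the published decision rules: detection failure in > 10% of
#' samples, DE at `p < 0.05` and `|log2FC| > 0.5`, module selection at
#' combined-score correlation above 0.6 with `p < 0.05`, pair filtering at a
#' 20% minority fraction, univariate screen at `p < 0.05`, and cutoff
#' selection on the 3-year time-dependent ROC.
#'
#' @param seed integer seed driving every random step (mandatory).
#' @param max_undetected_frac detection filter threshold.
#' @param de_p,de_lfc differential-expression thresholds.
#' @param ssgsea_alpha rank-weight exponent for the infiltration scores.
#' @param candidate_betas,target_r2 soft-threshold scan.
#' @param min_module_size,cut_height module detection.
#' @param module_r_min,module_p_max immune-module selection.
#' @param min_minor_frac pair-filter minority fraction (domain `[0, 0.5]`).
#' @param screen_p univariate Cox screen threshold.
#' @param cv_folds,cv_repeats Lasso-Cox repeated cross-validation.
#' @param cv_rule penalty rule, `"1se"` (default) or `"min"`; when the
#'   one-standard-error model is empty the pipeline falls back to the
#'   deviance minimum with a warning.
#' @param roc_horizon_years horizon (years) for cutoff selection.
#' @param eval_horizon_years horizons (years) for ROC evaluation.
#' @param bootstrap_B bootstrap resamples for the nomogram concordance.
#' @param calibration_bins calibration-curve quantile bins.
#' @param out_dir optional directory where intermediates are written.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            max_undetected_frac = 0.10,
                            de_p = 0.05, de_lfc = 0.5,
                            ssgsea_alpha = 0.25,
                            candidate_betas = 1:20, target_r2 = 0.85,
                            min_module_size = 30, cut_height = 0.99,
                            module_r_min = 0.6, module_p_max = 0.05,
                            min_minor_frac = 0.20,
                            screen_p = 0.05,
                            cv_folds = 10, cv_repeats = 25,
                            cv_rule = c("1se", "min"),
                            roc_horizon_years = 3,
                            eval_horizon_years = c(1, 3, 5),
                            bootstrap_B = 200,
                            calibration_bins = 3,
                            out_dir = NULL) {
  if (missing(seed)) {
    stop_pairsig("`seed` is mandatory in a pipeline configuration.",
                 "pairsig_validation_error")
  }
  cfg <- list(seed = as.integer(seed),
              max_undetected_frac = max_undetected_frac,
              de_p = de_p, de_lfc = de_lfc, ssgsea_alpha = ssgsea_alpha,
              candidate_betas = candidate_betas, target_r2 = target_r2,
              min_module_size = min_module_size, cut_height = cut_height,
              module_r_min = module_r_min, module_p_max = module_p_max,
              min_minor_frac = min_minor_frac, screen_p = screen_p,
              cv_folds = cv_folds, cv_repeats = cv_repeats,
              cv_rule = match.arg(cv_rule),
              roc_horizon_years = roc_horizon_years,
              eval_horizon_years = eval_horizon_years,
              bootstrap_B = bootstrap_B,
              calibration_bins = calibration_bins,
              out_dir = out_dir)
  assert_scalar_number(cfg$max_undetected_frac, "max_undetected_frac", 0, 1)
  assert_scalar_number(cfg$de_p, "de_p", 0, 1, strict_lower = TRUE)
  assert_scalar_number(cfg$de_lfc, "de_lfc", 0)
  assert_scalar_number(cfg$min_minor_frac, "min_minor_frac", 0, 0.5)
  assert_scalar_number(cfg$screen_p, "screen_p", 0, 1, strict_lower = TRUE)
  assert_scalar_number(cfg$module_r_min, "module_r_min", 0, 1)
  assert_scalar_number(cfg$module_p_max, "module_p_max", 0, 1,
                       strict_lower = TRUE)
  assert_scalar_number(cfg$roc_horizon_years, "roc_horizon_years", 0,
                       strict_lower = TRUE)
  assert_scalar_number(cfg$cv_folds, "cv_folds", 2, 100)
  assert_scalar_number(cfg$cv_repeats, "cv_repeats", 1, 10000)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stage_run <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop_pairsig(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                 "pairsig_stage_error")
  })
}

clinical_design <- function(clinical, risk_group = NULL) {
  d <- tibble::tibble(
    age = clinical$age,
    gender = as.numeric(clinical$gender == "M"),
    tnm = as.numeric(clinical$tnm_stage))
  if (!is.null(risk_group)) d$risk <- as.numeric(risk_group == "high")
  d
}

#' Run the full gene-pair signature pipeline
#'
#' Executes, in order: detection filter, mutation-stratified differential
#' expression, stromal/immune/combined infiltration scoring, soft-threshold
#' co-expression modules with module-trait statistics, immune-module gene
#' selection, pair construction and filtering, univariate Cox screen,
#' Lasso-Cox selection with repeated cross-validation, cutoff selection on
#' the time-dependent ROC, risk stratification with Kaplan-Meier/log-rank
#' and univariate+multivariable Cox evaluation, multi-horizon ROC and
#' concordance, and a nomogram with calibration and bootstrap concordance.
#' Identical configuration and seed give identical results.
#'
#' @param expr genes x samples matrix (training cohort).
#' @param clinical clinical tibble (see [read_clinical()]) aligned by
#'   `sample_id` to the expression columns.
#' @param stromal_set,immune_set gene sets for the infiltration scores.
#' @param config a [pipeline_config()].
#' @param validation_expr optional second cohort joining the detection filter.
#' @return object of class `pairsig_run`: a list of per-stage results,
#'   stage record counts, the fitted `pair_signature` and the resolved
#'   configuration.
#' @export
run_pipeline <- function(expr, clinical, stromal_set, immune_set, config,
                         validation_expr = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  assert_expression_matrix(expr)
  clinical <- clinical[match(colnames(expr), clinical$sample_id), ]
  if (anyNA(clinical$sample_id)) {
    stop_pairsig("`clinical` does not cover every expression sample.",
                 "pairsig_validation_error")
  }
  with_preserved_rng({
    set.seed(config$seed)
    counts <- list(genes_in = nrow(expr))

    filtered <- stage_run("detection_filter", {
      if (is.null(validation_expr)) {
        filter_detected(expr, max_undetected_frac = config$max_undetected_frac)
      } else {
        filter_detected(expr, validation_expr,
                        max_undetected_frac = config$max_undetected_frac)
      }
    })
    counts$genes_detected <- nrow(filtered)

    de <- stage_run("differential_expression",
      differential_expression(filtered, clinical$mutation,
                              p_thresh = config$de_p,
                              lfc_thresh = config$de_lfc))
    deg <- de$gene[de$passed]
    counts$de_genes <- length(deg)
    if (length(deg) < config$min_module_size) {
      stop_pairsig(sprintf("[stage differential_expression] only %d DE genes; too few for module detection (min module size %d). Consider relaxing `de_p`/`de_lfc`.",
                           length(deg), config$min_module_size),
                   "pairsig_stage_error")
    }

    scores <- stage_run("immune_scoring",
      estimate_scores(filtered, stromal_set, immune_set,
                      alpha = config$ssgsea_alpha))

    deg_expr <- filtered[deg, , drop = FALSE]
    soft <- stage_run("soft_threshold",
      pick_soft_threshold(deg_expr, candidate_betas = config$candidate_betas,
                          target_r2 = config$target_r2))
    tom <- stage_run("topological_overlap",
      topological_overlap(deg_expr, soft$beta))
    modules <- stage_run("module_detection",
      detect_modules(tom, min_module_size = config$min_module_size,
                     cut_height = config$cut_height))
    assignment <- stage_run("module_traits",
      module_trait_statistics(deg_expr, modules, scores))
    irgs <- stage_run("module_selection",
      select_immune_module(assignment, trait = "estimate",
                           r_min = config$module_r_min,
                           p_max = config$module_p_max))
    counts$irgs <- length(irgs)
    if (length(irgs) < 2) {
      stop_pairsig("[stage module_selection] no immune-related module passed selection; the pipeline halts before pairing.",
                   "pairsig_stage_error")
    }

    pim <- stage_run("pair_construction", build_pairs(filtered, irgs))
    counts$pairs_built <- nrow(pim)
    pim <- stage_run("pair_filter",
      filter_pairs(pim, min_minor_frac = config$min_minor_frac))
    counts$pairs_filtered <- nrow(pim)

    screen <- stage_run("univariate_screen",
      univariate_screen(pim, clinical$os_time, clinical$os_event,
                        p_max = config$screen_p))
    counts$pairs_screened <- nrow(screen)
    if (nrow(screen) == 0) {
      stop_pairsig("[stage univariate_screen] no pair passed the univariate screen.",
                   "pairsig_stage_error")
    }

    lasso <- stage_run("lasso_cox",
      lasso_cox(t(pim[screen$pair_label, , drop = FALSE]),
                clinical$os_time, clinical$os_event,
                n_folds = config$cv_folds, n_repeats = config$cv_repeats,
                seed = config$seed, cv_rule = config$cv_rule))
    if (length(lasso$coefficients) == 0 && config$cv_rule == "1se") {
      warn("The one-standard-error penalty selected an empty model; falling back to the CV-deviance minimum.")
      lasso <- stage_run("lasso_cox",
        lasso_cox(t(pim[screen$pair_label, , drop = FALSE]),
                  clinical$os_time, clinical$os_event,
                  n_folds = config$cv_folds, n_repeats = config$cv_repeats,
                  seed = config$seed, cv_rule = "min"))
    }
    if (length(lasso$coefficients) == 0) {
      stop_pairsig("[stage lasso_cox] the selected penalty zeroed every coefficient.",
                   "pairsig_stage_error")
    }
    counts$pairs_selected <- length(lasso$coefficients)
    sel <- pair_label_genes(names(lasso$coefficients))
    signature <- pair_signature(
      tibble::tibble(gene_a = sel$gene_a, gene_b = sel$gene_b,
                     coefficient = unname(lasso$coefficients)))

    risk <- stage_run("risk_scoring", risk_score(filtered, signature))
    roc_cut <- stage_run("cutoff_selection",
      time_dependent_roc(risk$score, clinical$os_time, clinical$os_event,
                         horizon = config$roc_horizon_years * 365.25))
    signature$cutoff <- roc_cut$best_cutoff
    risk <- classify_risk(risk, signature$cutoff)

    evaluation <- stage_run("evaluation", {
      both <- length(unique(risk$group)) == 2
      lr <- if (both) {
        logrank_test(risk$group, clinical$os_time, clinical$os_event)
      } else NULL
      km <- lapply(split(seq_len(nrow(risk)), risk$group), function(idx) {
        km_estimate(clinical$os_time[idx], clinical$os_event[idx])
      })
      rocs <- lapply(config$eval_horizon_years, function(yy) {
        tryCatch(time_dependent_roc(risk$score, clinical$os_time,
                                    clinical$os_event, horizon = yy * 365.25),
                 error = function(e) NULL)
      })
      names(rocs) <- paste0("year", config$eval_horizon_years)
      cc <- concordance_index(risk$score, clinical$os_time, clinical$os_event)
      ok_stage <- !is.na(clinical$tnm_stage)
      design <- clinical_design(clinical[ok_stage, ], risk$group[ok_stage])
      uni <- lapply(names(design), function(v) {
        tryCatch(tidy(cox_fit(design[v], clinical$os_time[ok_stage],
                              clinical$os_event[ok_stage])),
                 error = function(e) NULL)
      })
      multi <- tryCatch(cox_fit(design, clinical$os_time[ok_stage],
                                clinical$os_event[ok_stage]),
                        error = function(e) NULL)
      list(logrank = lr, km = km, roc = rocs, c_index = cc,
           cox_univariate = dplyr::bind_rows(uni),
           cox_multivariate = multi)
    })

    nomo <- stage_run("nomogram", {
      ok_stage <- !is.na(clinical$tnm_stage)
      design <- clinical_design(clinical[ok_stage, ], risk$group[ok_stage])
      multi <- evaluation$cox_multivariate
      if (is.null(multi)) {
        NULL
      } else {
        model <- fit_nomogram(multi, design)
        calib <- tryCatch(
          calibration_curve(model, design, clinical$os_time[ok_stage],
                            clinical$os_event[ok_stage],
                            t = config$roc_horizon_years * 365.25,
                            n_bins = config$calibration_bins),
          error = function(e) NULL)
        boot <- bootstrap_cindex(
          predict(model, design, type = "lp"),
          clinical$os_time[ok_stage], clinical$os_event[ok_stage],
          B = config$bootstrap_B, seed = config$seed)
        list(model = model, calibration = calib, bootstrap_c = boot)
      }
    })

    run <- structure(list(
      config = config, counts = counts, filtered_genes = rownames(filtered),
      de = de, scores = scores, soft_threshold = soft,
      assignment = assignment, irgs = irgs, screen = screen, lasso = lasso,
      signature = signature, cutoff_roc = roc_cut, risk = risk,
      evaluation = evaluation, nomogram = nomo), class = "pairsig_run")
    if (!is.null(config$out_dir)) write_run(run, config$out_dir)
    run
  })
}

#' @export
print.pairsig_run <- function(x, ...) {
  cat("<pairsig_run>\n")
  cat(sprintf("  genes: %d -> detected %d -> DE %d -> immune module %d\n",
              x$counts$genes_in, x$counts$genes_detected, x$counts$de_genes,
              x$counts$irgs))
  cat(sprintf("  pairs: %d built -> %d filtered -> %d screened -> %d in signature\n",
              x$counts$pairs_built, x$counts$pairs_filtered,
              x$counts$pairs_screened, x$counts$pairs_selected))
  cat(sprintf("  cutoff = %.4g; C-index = %.3f\n", x$signature$cutoff,
              x$evaluation$c_index))
  if (!is.null(x$evaluation$logrank)) {
    cat(sprintf("  log-rank p = %.3g\n", x$evaluation$logrank$p_value))
  }
  invisible(x)
}

#' @export
glance.pairsig_run <- function(x, ...) {
  aucs <- vapply(x$evaluation$roc, function(r)
    if (is.null(r)) NA_real_ else r$auc, 0)
  out <- tibble::tibble(
    n_de_genes = x$counts$de_genes, n_irgs = x$counts$irgs,
    n_pairs_signature = x$counts$pairs_selected,
    cutoff = x$signature$cutoff, c_index = x$evaluation$c_index,
    logrank_p = if (is.null(x$evaluation$logrank)) NA_real_ else
      x$evaluation$logrank$p_value)
  for (nm in names(aucs)) out[[paste0("auc_", nm)]] <- aucs[[nm]]
  out
}

#' Write the run's intermediates and a JSON report to a directory
#' @param run a `pairsig_run`.
#' @param dir output directory.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(run$de, file.path(dir, "differential_expression.tsv"))
  readr::write_tsv(run$scores, file.path(dir, "infiltration_scores.tsv"))
  readr::write_tsv(run$assignment$modules, file.path(dir, "modules.tsv"))
  readr::write_tsv(run$assignment$module_trait,
                   file.path(dir, "module_trait.tsv"))
  readr::write_tsv(run$screen, file.path(dir, "univariate_screen.tsv"))
  write_signature(run$signature, file.path(dir, "signature.tsv"))
  readr::write_tsv(run$risk, file.path(dir, "risk.tsv"))
  report <- c(run$counts, as.list(glance(run)))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Score and stratify a cohort with the packaged published signature
#'
#' Applies a pair signature (by default the packaged 26-pair LUSC signature
#' with its published cutoff of -0.024) to an expression matrix, classifies
#' samples into high and low risk, and — when a clinical table is supplied —
#' evaluates the split by Kaplan-Meier, log-rank and concordance.
#'
#' @param expr genes x samples matrix containing every signature gene
#'   (or set `allow_missing`).
#' @param clinical optional clinical tibble aligned by `sample_id`.
#' @param signature a [pair_signature()]; defaults to [lusc_signature()].
#' @param allow_missing forwarded to [risk_score()].
#' @return object of class `risk_assessment`: list with `scores` (tibble
#'   sample_id, score, group), `cutoff` and (when clinical is given)
#'   `evaluation` (km, logrank, c_index).
#' @export
apply_published_signature <- function(expr, clinical = NULL,
                                      signature = lusc_signature(),
                                      allow_missing = FALSE) {
  if (is.na(signature$cutoff)) {
    stop_pairsig("The signature carries no cutoff; classify with `classify_risk()` directly.",
                 "pairsig_validation_error")
  }
  scores <- risk_score(expr, signature, allow_missing = allow_missing)
  scores <- classify_risk(scores, signature$cutoff)
  evaluation <- NULL
  if (!is.null(clinical)) {
    clinical <- clinical[match(scores$sample_id, clinical$sample_id), ]
    both <- length(unique(scores$group)) == 2
    evaluation <- list(
      km = lapply(split(seq_len(nrow(scores)), scores$group), function(idx)
        km_estimate(clinical$os_time[idx], clinical$os_event[idx])),
      logrank = if (both) logrank_test(scores$group, clinical$os_time,
                                       clinical$os_event) else NULL,
      c_index = concordance_index(scores$score, clinical$os_time,
                                  clinical$os_event))
  }
  structure(list(scores = scores, cutoff = signature$cutoff,
                 signature = signature, evaluation = evaluation),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  tab <- table(x$scores$group)
  cat(sprintf("<risk_assessment> %d samples (high %d / low %d), cutoff %.4g\n",
              nrow(x$scores), tab["high"] %||% 0, tab["low"] %||% 0, x$cutoff))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  C-index %.3f", x$evaluation$c_index))
    if (!is.null(x$evaluation$logrank)) {
      cat(sprintf(", log-rank p = %.3g", x$evaluation$logrank$p_value))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
tidy.risk_assessment <- function(x, ...) x$scores

#' @export
glance.risk_assessment <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    n_high = sum(x$scores$group == "high"),
    n_low = sum(x$scores$group == "low"),
    cutoff = x$cutoff,
    c_index = if (is.null(x$evaluation)) NA_real_ else x$evaluation$c_index,
    logrank_p = if (is.null(x$evaluation) || is.null(x$evaluation$logrank))
      NA_real_ else x$evaluation$logrank$p_value)
}
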