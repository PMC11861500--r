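---
title: "Gene-pair prognostic signatures: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic signatures: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsig)
```

## Why relative-rank pairs

Bulk tumor expression cohorts are frequently assembled across platforms,
batches and normalization pipelines, so the absolute value of a gene's
measurement is not comparable between samples. The binary indicator
`P_ab = 1(x_a > x_b)` compares two genes *within* one sample, and is
therefore unchanged by any per-sample strictly increasing transform of the
data. A signature built from such indicators — a coefficient-weighted sum
`S = Σ c_k P_k` — transfers between cohorts without renormalization. This
invariance is not merely assumed: it is asserted by property tests that
apply log, affine, rank and polynomial transforms to random cohorts and
require bit-identical indicators, scores and risk groups.

Ties (`x_a == x_b`) are scored 0. This is the strict reading of "higher
marked as 1, otherwise 0"; on continuous data ties are rare, and the
convention only matters for zero-inflated values. Scores exactly at the
classification cutoff go to the low-risk group; that boundary convention is
the package's own and is documented rather than attributed to any source.

## The pipeline and its stages

`run_pipeline()` chains the stages; each is also exported on its own.

1. **Detection filter** (`filter_detected`): a gene is kept only if it is
   detected (value > 0) in at least 90% of samples in *every* supplied
   cohort. Removal requires strictly more than `max_undetected_frac = 0.10`
   undetected, so exactly 10% survives — tests pin this boundary.
2. **Differential expression** (`differential_expression`): per-gene Welch
   t-tests between mutant and wild-type samples on log2-scale values;
   `log2fc` is the group-mean difference, and a gene passes at
   `p < 0.05` and `|log2fc| > 0.5`. Raw p-values are the default because the
   decision rule is stated without adjustment; Benjamini–Hochberg is
   available behind `adjust = TRUE`. A moderated-variance mode
   (`shrink_var = TRUE`) squeezes group variances toward their across-gene
   mean with a method-of-moments prior weight, for sensitivity analysis with
   small groups; the default stays Welch because the decision thresholds,
   not the variance model, define the rule.
3. **Infiltration scores** (`ssgsea_score`, `estimate_scores`): single-sample
   rank-based enrichment. Genes are ranked by expression (average ranks for
   ties); walking the ranking from the top, the score accumulates the
   difference between the weighted in-set ECDF (weights `rank^alpha`,
   `alpha = 0.25`, normalized within the set) and the unweighted out-of-set
   ECDF. The combined score is stromal + immune, exactly. No cross-sample
   normalization is applied, matching the convention of raw single-sample
   enrichment sums; a min-max rescaling flag exists for plotting only.
4. **Co-expression modules** (`pick_soft_threshold`, `topological_overlap`,
   `detect_modules`, `module_trait_statistics`, `select_immune_module`):
   unsigned adjacency `|cor|^β` with Pearson correlation throughout; the
   power is the smallest reaching scale-free fit R² ≥ 0.85 (signed log-log
   regression of connectivity frequency over 10 logarithmic bins, empty bins
   dropped), else the best-fitting power with a warning. The topological
   overlap matrix is clustered by average linkage on `1 − TOM` with a static
   cut; clusters under `min_module_size = 30` stay unassigned ("grey").
   A static cut replaces the dynamic hybrid tree cut: the single-module
   selection this pipeline needs does not justify the heuristic complexity,
   the cut height and minimum size are exposed in the configuration, and the
   planted-block recovery tests are agnostic to the cut method. Module
   eigengenes are first principal components of the standardized module
   submatrix, unit norm, sign fixed so the mean correlation with member
   genes is non-negative. A module qualifies as immune-related when
   `|r| > 0.6` with `p < 0.05` against the combined score — the absolute
   value with positive-direction preference is a documented interpretation,
   since the stated rule does not specify a sign — and among qualifiers the
   largest immune-score correlation wins.
5. **Pair construction and filtering** (`build_pairs`, `filter_pairs`):
   all unordered combinations of the module genes, alphabetically oriented
   and lexicographically listed. A pair is dropped if its indicator is
   constant across samples (zero dispersion) or if its minority value occurs
   in under 20% of samples. The dispersion criterion is implemented as
   zero mean absolute deviation rather than a median-based MAD because the
   median-based statistic is identically zero on any unbalanced binary row —
   and on every row when the sample count is odd — which would discard the
   entire candidate set.
6. **Signature fitting** (`univariate_screen`, `lasso_cox`): per-pair Cox
   models (Efron tie correction; Wald p-values — the screen statistic is not
   otherwise specified, and Wald is reported by every standard
   implementation) keep pairs at `p < 0.05`; the survivors enter an
   L1-penalized Cox fit over a geometric 100-point penalty grid down to 0.01
   of the all-zero penalty. The penalty is chosen from cross-validated
   partial-likelihood deviance averaged over repeated fold splits
   ("1000 simulations" is read as repeated cross-validation; the package
   default is 25 repeats, which stabilizes the curve at desk scale, and the
   full thousand is one argument away). The default selection rule is the
   one-standard-error rule rather than the deviance minimum: because the
   univariate screen runs on the same data, the deviance minimum inherits
   the screen's selection bias and admits many null pairs (measured: ~12
   selected pairs on pure-noise cohorts, versus 0 with the 1-SE rule, at a
   cost of roughly one planted pair in recovery simulations). `cv_rule =
   "min"` restores the plain minimizer, and the pipeline falls back to it
   with a warning if the 1-SE model is empty.
7. **Risk stratification and evaluation** (`time_dependent_roc`,
   `classify_risk`, `km_estimate`, `logrank_test`, `concordance_index`):
   the cutoff maximizes Youden's J on the 3-year cumulative-case /
   dynamic-control ROC; ties in J break toward the lower cutoff. Censoring
   enters through inverse-probability-of-censoring weights from the
   Kaplan–Meier estimate of the censoring distribution (cases weighted by
   `1/G(T⁻)`, controls by `1/G(t)`); with no censoring the curve reduces
   exactly to the empirical Mann–Whitney AUC, which is one of the oracle
   tests. High risk means score strictly above the cutoff and worse
   survival.
8. **Nomogram** (`fit_nomogram`, `calibration_curve`, `bootstrap_cindex`):
   points are affine per covariate, `100 · β_j (x_j − ref_j) / max_k |β_k ·
   range_k|`, with the reference taken at the covariate value minimizing
   `β_j x_j` so all point contributions are non-negative and the dominant
   covariate spans exactly 0–100. (Anchoring at the covariate minimum
   regardless of coefficient sign would produce negative point axes.)
   Predicted survival is `S_ref(t)^exp(lp − lp_ref)` with a Breslow
   baseline. TNM enters as ordinal 1–4, gender as a binary indicator, age in
   years; the signature enters as the binary risk group by default, with the
   continuous score available by building the design matrix directly.
   Calibration bins samples by predicted-survival quantiles and compares
   with the within-bin Kaplan–Meier estimate at the horizon; bins whose
   subjects are all censored before the horizon are flagged, never imputed.
9. **Downstream comparisons** (`deconvolve`, `compare_groups`, `hub_genes`,
   `drug_correlation`): the deconvolution engine is a constrained
   (non-negative) least-squares surrogate normalized to the unit simplex —
   it satisfies the published engines' output contract and is exactly
   testable on synthetic mixtures, but reproduces neither support-vector
   weighting nor permutation significance, and is labeled as a surrogate
   wherever it appears. Group comparisons use the Wilcoxon rank-sum test,
   exact for combined n ≤ 25 without ties. Hub genes are degree-filtered
   (≥ 5, inclusive) on the candidate-induced subgraph; "node count" is read
   as node degree, the alternative (component size) being documented here
   rather than guessed.

## The synthetic cohort generator

`simulate_cohort()` draws log2-like expression as
`baseline + loading · f (immune block) + direction · effect · mutation (DE
genes) + noise`, zero-inflates with probability 0.02 and clamps at zero so
"not detected" arises naturally for the detection filter. Survival follows a
Weibull proportional-hazards model (shape 1 = exponential baseline, the
simplest PH-compatible choice; the shape is exposed) with linear predictor
`Σ w_k P_k + γ f`, where `f` is the latent immune factor. Censoring is an
independent exponential time whose rate is solved numerically so the
realized censoring fraction hits the target — avoiding
administrative-censoring edge cases — and tests require the realized
fraction within ±0.05 at n ≥ 500. TNM stage is rank-binned from the linear
predictor plus unit noise into the cohort's marginal stage frequencies, so
multivariable models have a genuinely prognostic ordinal covariate.

Defaults are calibrated to the cohort structure the generator emulates: a
mutant fraction of 44/504, about 27% of differential genes shifted upward,
baseline hazard 0.15/year, 30% censoring, and immune-factor loadings of
1.5–2.5 over unit noise. The loading range follows the reported strength of
immune-infiltration modules (module-membership correlations near 0.9):
weaker loadings produce gene–gene correlations around 0.5, under which no
co-expression module forms at any soft-threshold power and the module stage
cannot function at all. Gene symbols are synthetic (`g0001`…), and
`choose_planted_pairs()` exploits the fact that `true_pairs` affects only
the survival draw: simulating once, choosing variable pairs, and
re-simulating under the same seed yields identical expression with
pair-driven survival.

What the generator does **not** emulate: read counts and library-size
effects, batch structure, gene-length or GC biases, correlated censoring,
and any single-cell structure. Passing tests therefore demonstrate that the
machinery is correct and recovers planted structure under the stated noise
model — not that any particular biological cohort satisfies that model.
The expression unit of real matrices (counts vs. FPKM vs. arrays) is left
generic: everything downstream of the detection filter is rank-based or
works on log-scale differences, and this is documented rather than
resolved.

## Numerical choices and degenerate inputs

* Ranks use average ties everywhere (deterministic and symmetric); the
  enrichment walk breaks ordering ties by gene name for reproducibility.
* Cox fits use the Efron tie correction; perfect separation is detected and
  reported as an error naming the covariate, as are constant covariates,
  zero events, and non-positive times.
* `filter_pairs` is idempotent; `build_pairs` output is independent of the
  input gene order; both are covered by tests.
* Duplicate gene rows in expression files collapse by mean with a warning;
  missing expression cells are an error — the pairing indicator is undefined
  on missing values, and silent imputation would change score scales.
* Missing signature genes on external data are a hard error by default;
  `allow_missing` drops the affected pairs with a warning that the score
  scale is no longer comparable.
* Unknown TNM tokens become missing values and are excluded from
  stage-using models with a warning, never dropped from the cohort.
* Bootstrap resamples with no comparable pairs are redrawn, counted, and
  capped at ten times the requested resamples.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen for thorough yet fast
desk-scale runs: distributional checks on 2000–6000 genes; type-I error of
the log-rank split over 400 null cohorts of n = 150; planted-pair recovery
on ten seeded cohorts of n = 300 with ten planted pairs (|w| = 0.8) among
roughly 500 filtered candidates and 30% censoring; module recovery of a
50-gene planted block among 200 genes; nomogram self-calibration at
n = 1000. Cross-validation in the recovery tests uses 5 repeated fold
splits; the package default is 25, and 1000 remains available.

## Known limitations

* The co-expression stage holds the full correlation and TOM matrices in
  memory; it is intended for filtered candidate sets (hundreds to a few
  thousand genes), not whole transcriptomes.
* Module merging by eigengene correlation, dynamic tree cutting, and
  topology-preservation statistics are out of scope.
* The deconvolution surrogate shares only the output contract with
  support-vector-regression engines; fractions from the two should not be
  mixed in one analysis.
* The univariate screen and signature evaluation run on the training cohort
  (as the emulated workflow does); reported training-set AUCs and log-rank
  p-values are optimistic by construction, and external validation data
  should be scored with the frozen signature only.
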