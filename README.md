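# pairsig

Relative-rank gene-pair prognostic signatures for bulk tumor expression
cohorts, with the full analysis pipeline around them: mutation-stratified
differential expression, single-sample stromal/immune scoring, weighted
co-expression module screening, penalized Cox signature fitting,
time-dependent ROC risk stratification, nomogram evaluation, and downstream
immune-infiltration and drug-response comparisons.

The package is aimed at analysts building or validating prognostic
signatures from gene-by-sample expression matrices with right-censored
survival — the situation where measurements come from different platforms or
normalizations and absolute expression values are not comparable across
samples. It ships a seeded synthetic-cohort generator with known ground
truth, so the entire pipeline is testable without any data download, and a
published 26-pair lung squamous cell carcinoma (LUSC) signature as a
packaged fixture.

## The model

For a sample with expression vector *x* and an ordered gene pair (*a*, *b*),
the pair indicator is

    P_ab(x) = 1  if  x_a > x_b,   0 otherwise  (ties are 0).

Indicators depend only on the within-sample ordering of two genes, so they
are invariant under any per-sample strictly increasing transform of the
data — normalization, log-scaling, and rank transforms all leave them
unchanged. A pair signature is a set of pairs with Cox coefficients
*c₁…c_K*; the per-sample risk score is

    S(x) = Σ_k c_k · P_k(x),

and samples are called high-risk when *S* exceeds a cutoff chosen by
Youden's J on the 3-year time-dependent ROC curve. Candidate pairs are built
from immune-related genes (selected as the co-expression module most
correlated with a combined stromal+immune infiltration score), filtered for
variation (minority indicator value in ≥ 20% of samples), screened by
univariate Cox regression, and reduced to a sparse signature by
Lasso-penalized Cox regression with repeated cross-validation.

## Worked example

Simulate a cohort of 300 tumors in which survival is driven by ten planted
gene pairs (weights ±0.8) on top of a 52-gene immune block, then run the
full pipeline:

```r
library(pairsig)

spec <- cohort_spec(n_samples = 300, n_genes = 120, n_immune_block = 52,
                    n_de_genes = 60, censor_rate = 0.3, seed = 1)
base    <- simulate_cohort(spec)
planted <- choose_planted_pairs(base, n_pairs = 10, min_minor_frac = 0.3,
                                weights = rep(c(0.8, -0.8), 5))
spec$true_pairs <- planted
cohort  <- simulate_cohort(spec)      # same expression, survival now pair-driven
fx      <- simulate_fixtures(spec)    # gene sets, mixtures, drug panel, edges

cfg <- pipeline_config(seed = 1, cv_repeats = 5, min_module_size = 20)
run <- run_pipeline(cohort$expression, cohort$clinical,
                    fx$gene_sets$stromal, fx$gene_sets$immune, cfg)
run
#> <pairsig_run>
#>   genes: 120 -> detected 120 -> DE 38 -> immune module 38
#>   pairs: 703 built -> 305 filtered -> 97 screened -> 3 in signature
#>   cutoff = 0.09811; C-index = 0.674
#>   log-rank p = 1.99e-12
```

Reading the output: all 120 genes pass the detection filter; 38 are
differentially expressed between the mutation-defined groups; those 38 form
one immune-related module, giving 703 candidate pairs, of which 305 vary
enough to keep, 97 pass the univariate Cox screen, and 3 survive the
penalized fit. The fitted signature splits the cohort into high/low risk
groups whose survival separates at log-rank p ≈ 2e-12, with 1/3/5-year
time-dependent AUCs of 0.73 / 0.71 / 0.73 (see `glance(run)`). The
differential-expression stage is the bottleneck for recovering planted pairs
here: only pairs whose both genes pass the DE thresholds can enter the
candidate pool. Fitting from the immune block directly (`build_pairs` →
`filter_pairs` → `univariate_screen` → `lasso_cox`) recovers 8–10 of the 10
planted pairs (this is what `scripts/acceptance.R` measures).

The packaged 26-pair LUSC signature applies to any matrix containing its 39
genes:

```r
sig <- lusc_signature()
sig
#> <pair_signature> 26 pairs over 39 genes; cutoff = -0.024
scores <- risk_score(expr, sig)            # tibble: sample_id, score
groups <- classify_risk(scores, sig$cutoff)
```

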