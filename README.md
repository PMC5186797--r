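# proliflux

Predicting proliferation rates for expression-only tumor cohorts from
cell-line training data, and turning those rates into per-sample
metabolic flux predictions.

Tumor compendia profile gene expression at scale but do not measure how
fast each sample proliferates, while cancer cell-line panels provide
both expression and doubling times. proliflux implements the full
transfer strategy for systems biologists working at that interface:

1. **Cross-platform harmonization** — mean log2 expression on the
   cohort platform is modeled as *e*ᵀ = α·*e*ᴺ + β, with α fitted as a
   zero-intercept slope on the cohort's dual-platform (array + RNA-seq)
   subset and β as the mean shift of a same-platform comparison; genes
   whose corrected means disagree by ≥ 1 log2 unit (2-fold) in either
   comparison are discarded.
2. **An interaction LASSO predictor** — a first-order L1 fit selects
   genes with clearly non-zero coefficients; their *k*(*k*−1)/2 pairwise
   products and *k* squares feed a pure second-order L1 fit; the
   smallest quartile of non-zero coefficients is cut and the model
   refit. Performance is reported as mse, rmse, mae, mre and R² for
   training and leave-one-out cross-validation.
3. **Parsimonious FBA** — each sample's predicted rate *r*ₚ constrains
   its panel's irreversible metabolic model via
   min Σᵢ vᵢ s.t. S·v = 0, vᵢ ≥ 0, v_p = r_p;
   samples with non-positive rates are skipped, fluxes zero in every
   sample are dropped.
4. **Panel statistics** — per-flux specificity
   s = log₂ μ_panel − log₂ μ_other, an |s|-ranked list across all
   panels and fluxes, and a GSEA-style enrichment score per pathway
   normalized by 100 pathway-label permutations
   (NES = ES / mean ES_perm) with two-tailed empirical p-values.

Seeded synthetic generators (cell-line panels, dual-platform cohorts,
toy metabolic models with panel-specific reaction removals) carry known
ground truth, so every stage — and the composed pipeline — is testable
without any external download.

## Worked example

Train and validate the staged predictor on a simulated 57-line panel,
then solve one panel's flux problem:

```r
library(proliflux)

truth <- ground_truth(seed = 1)
truth
#> <ground_truth> 500 genes (400 conserved), 3 signal pair(s),
#>   intercept 0.02, noise_sd 0.001, alpha 1.15, beta 0.35

panel <- simulate_cell_line_panel(truth, n_lines = 57, seed = 2)
cv <- loocv_evaluate(panel$expression, panel$rates$rate, seed = 1)
cv
#> <loocv_result> mode 'fixed_features', order 'second_cutoff'
#> # A tibble: 2 × 7
#>           mse     rmse      mae     mre r_squared strategy   order
#> 1 0.000000119 0.000345 0.000275 0.00527     0.998 train      second_cutoff
#> 2 0.000000389 0.000624 0.000510 0.00978     0.993 validation second_cutoff
```

The validation row is the honest one: R² = 0.993 and a mean relative
error just under 1 % mean the leave-one-out predictions track the
simulated rates (~0.02–0.07 h⁻¹) almost perfectly at the default noise
level; `tidy(cv$fit$predictor)` lists the recovered gene-pair features.

```r
models <- simulate_toy_models(n_panels = 3)
sol <- pfba_fixed_growth(to_irreversible(models$panel_2), r_p = 0.02)
sol
#> <pfba_solution> optimal, total flux 0.36, 13 active reaction(s)
head(tidy(sol)[tidy(sol)$flux > 0, ], 4)
#> # A tibble: 4 × 2
#>   reaction  flux
#> 1 EX_A      0.06
#> 2 EX_N      0.02
#> 3 PPP1      0.04
#> 4 PPP2      0.04
```

Panel 2's model lacks the glycolysis-like chain, so achieving a
proliferation flux of 0.02 h⁻¹ routes all hexose flux through the
pentose-shunt reactions (PPP1–PPP3) — the panel-specific signal that
`compute_specificity()` and `normalize_enrichment()` later surface as
the top-NES pathway. `run_pipeline(write_synthetic_fixture("fixtures"))`
composes all stages from files on disk and writes every intermediate as
CSV plus a JSON manifest; `autoplot()` methods visualize LOOCV fits,
filter reports, flux matrices and enrichment results.

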