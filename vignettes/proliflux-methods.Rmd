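---
title: "Methods: from cell-line expression to cohort proliferation rates and metabolic fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cell-line expression to cohort proliferation rates and metabolic fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proliflux)
```

proliflux chains four pieces of methodology: cross-platform expression
harmonization, a sparse interaction regression for proliferation rates,
proliferation-constrained parsimonious flux balance analysis (pFBA), and
panel-level flux statistics. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions that were
genuinely open; it also describes exactly what the synthetic-data
generators emulate, and therefore what the package's tests do and do not
demonstrate about real data.

## The scientific setting

Cell-line compendia report measured proliferation rates (via doubling
times, rate = ln 2 / doubling time, in h⁻¹) together with microarray
expression; large tumor cohorts report expression — mostly RNA-seq, with
an array subset — but no proliferation measurements. The strategy is to
train a predictor of proliferation on the cell lines, transfer it to the
cohort through a cross-platform expression correction, and then use each
sample's predicted rate as the growth constraint of a parsimonious flux
balance problem on its cancer panel's metabolic model. Panel-specific
flux differences are finally summarized by a specificity score and a
GSEA-style pathway enrichment statistic.

## Cross-platform harmonization

Mean log2 expression of a gene on the cohort platform is modeled as an
affine function of its reference-platform value,
$e^T = \alpha\,e^N + \beta$, with $\alpha$ a platform factor and $\beta$
a dataset (sample-quantity) shift. The two parameters are deliberately
fitted from different data set combinations:

* $\alpha$ from the cohort's dual-platform subset — the same samples on
  both platforms imply $\beta = 0$, so $\alpha$ is the zero-intercept
  least-squares slope $\sum x y / \sum x^2$ over per-gene means;
* $\beta$ from the same-platform comparison between the reference and
  cohort datasets — the same platform implies $\alpha = 1$, so $\beta$
  is the mean per-gene difference.

A gene is *conserved* when it is present in all three datasets and its
corrected mean log2 expression agrees within `max_dist` (default 1, i.e.
a corrected maximal difference of 2-fold, strict inequality) in both
comparisons; the same-platform comparison corrects with $\beta$ alone,
the cross-platform comparison with the full $(\alpha, \beta)$ model.
All logarithms in the package are base 2; the equivalence of "distance
1" and "2-fold" relies on it.

Two design points deserve emphasis:

* **Refinement.** Genes without conserved expression bias the all-gene
  fits. `harmonize_platforms()` therefore refits $(\alpha, \beta)$ on
  the genes passing the filter and filters once more. On cohorts
  without platform noise the refined estimates equal the generating
  parameters to machine precision.
* **Correction direction.** The fitted model could correct the
  reference expression onto the cohort scale before training. An affine
  map of log values, however, turns a pure product-feature model into
  one that also needs first-order terms, so the pipeline instead maps
  cohort sequencing values back onto the reference scale by inverting
  the two fitted sub-models in sequence ($e = r/\hat\alpha -
  \hat\beta$) and trains the predictor on the reference-scale matrix.
  The information content is identical; the representation stays exact.

## The interaction predictor

Proliferation rates are regressed on gene expression with an
L1-penalized (LASSO) linear model, `glmnet` under the hood, with the
penalty strength chosen by 10-fold cross-validation minimizing the mean
squared error (folds seeded; features standardized internally for the
penalty and coefficients reported on the original scale). The staged
sequence is:

1. a first-order fit on all (conserved) genes;
2. selection of the genes with clearly non-zero coefficients
   (`tol = 1e-8`, configurable — the threshold is a numerical guard, not
   a biological parameter);
3. a pure second-order fit on the $k(k-1)/2$ pairwise products plus $k$
   squares of the selected genes' log2 values;
4. a coefficient cutoff: the smallest quartile (`q = 0.25`) of the
   non-zero absolute coefficients is removed and the model refit on the
   survivors.

The cutoff removes features at or below the interpolated `q` quantile of
the non-zero absolute coefficients, capping the number of drops at
`floor(q * n_nonzero)`: with only two or three non-zero coefficients the
smallest "quartile" is empty and nothing is dropped, which keeps the
rule faithful to "remove the smallest 25 %" without gutting an already
sparse model. The largest-coefficient feature is always retained, and
the model is refit (not merely truncated) because truncation alone
leaves the intercept sub-optimal. A model reduced to a single feature is
refit as unpenalized least squares, the limit of the penalty path.

Performance is reported as five metrics — mse, rmse, mae, mre (mean of
$|p-o|/|o|$ over non-zero observations) and $R^2$ — for the training
fit and for leave-one-out cross-validation (LOOCV); predictive claims
rest on the LOOCV row only. Two LOOCV modes exist: `fixed_features`
(default) freezes the selected interaction features and cutoff
survivors from a full-data pass and refits only the penalized
coefficients per fold; `nested` redoes the entire selection inside every
fold. The fixed mode mirrors how such pipelines are usually evaluated
but leaks a small amount of selection information into the folds; the
nested mode is unbiased and slower. Both are exposed, neither is hidden
behind the other.

Negative rate predictions are returned as-is and flagged; downstream
flux analysis skips those samples, reading them as "not proliferating".

## Parsimonious FBA at a fixed proliferation rate

Each cancer panel has one stoichiometric model with a proliferation
(biomass) reaction. After splitting every reversible reaction into
non-negative forward and backward halves, the flux distribution for a
sample with predicted rate $r_p$ is the solution of

$$\min \sum_i v_i \quad \text{s.t.}\quad S v = 0,\; v_i \ge 0,\; v_p = r_p,$$

the most economic flux distribution achieving the required growth. No
finite upper bounds are needed; the objective itself bounds the feasible
slice. The equality $v_p = r_p$ is encoded as an explicit constraint
row. The solver is the dense simplex method from the recommended `boot`
package, adequate and exact at the tested model sizes; a presolve first
eliminates reactions forced to zero by metabolite rows whose non-zero
coefficients share a single sign (no producer or no consumer at steady
state), which both shrinks the program and avoids degenerate pivots.

Because the program is homogeneous in $r_p$, `batch_pfba()` by default
solves each panel model once at a reference rate and rescales linearly
per sample (`recycle = TRUE`); `recycle = FALSE` solves every sample
from scratch and is used as the oracle in tests. pFBA minimizers need
not be unique in general; the package's own toy models are constructed
with strictly different route lengths so their optima are unique, and
properties on arbitrary models are asserted on objective values rather
than individual fluxes. Fluxes that are zero (tolerance `1e-9`,
configurable) in every sample are dropped before statistics.

## Panel specificity and pathway enrichment

For panel $p$ and reaction $i$, the specificity score is
$s_{pi} = \log_2(\mu_{pi} + \varepsilon) - \log_2(\mu_{oi} +
\varepsilon)$ with $\mu_{pi}$ the mean flux inside the panel and
$\mu_{oi}$ the mean over all other samples. The pseudocount
$\varepsilon$ (default `1e-9`, 0 available) makes the score defined for
the zero mean fluxes that routinely arise after panel-specific reaction
removals; at the default it perturbs non-zero scores only in the tenth
digit.

All (panel, reaction) scores are pooled and ranked by $|s|$ descending
(ties broken lexicographically so the ranking is deterministic). For a
pathway hitting $n_h$ of the $n$ entries, a running sum accumulates
$|s|/n_r$ per hit ($n_r$ = total $|s|$ over the pathway's entries) and
$1/(n-n_h)$ per miss; the enrichment score ES is the running
deviation's extreme of largest magnitude. The hit weights are absolute
specificity values — the list is ranked by absolute value, and signed
weights would make $n_r$ ill-defined. Both extremes can be requested
(`both = TRUE`) where the largest-magnitude reading is in doubt.

The normalized score is $\text{NES} = \text{ES}/\overline{\text{ES}}_{\text{perm}}$
over `n_perm = 100` random permutations of the pathway-label column
(the ranked $|s|$ values stay fixed, so each pathway keeps its $n_h$).
All permuted values enter the denominator mean regardless of sign; if
that mean is numerically zero (magnitude < 1e-12) the NES is reported
as undefined rather than divided. Empirical p-values are taken
separately per tail. NES above 1 marks a pathway enriched among the
panel-specific fluxes; below 1, one whose activity is homogeneous
across panels. Under random pathway assignment on lists with
realistically skewed $|s|$ the NES distribution centers near 1 and the
tail p-values are approximately uniform, which the test suite checks by
simulation.

## What the synthetic generators emulate

The generators provide ground-truth-known stand-ins for the three data
tiers:

* **Cell-line panel.** Log2 expression is Gaussian per gene around
  fixed means spanning 4–12 (the scale of RMA-normalized arrays),
  biological standard deviation 1 across lines. Proliferation rates are
  `intercept + Σ coef · e_i·e_j + noise`: by default three signal pairs
  drawn from the conserved genes with means confined to the
  well-quantified 7–9 band, coefficient magnitudes 2–5 × 10⁻⁴ with
  alternating signs, intercept 0.02 and rate noise sd 10⁻³ — yielding
  rates of roughly 0.02–0.07 h⁻¹, the magnitude implied by cancer
  cell-line doubling times of 10–35 h. A helper converts doubling times
  to rates (ln 2 / t); both scales are accepted, the rate scale is the
  default convention.
* **Dual-platform cohort.** Each sample carries latent reference-scale
  expression; its array platform observes the latent value plus the
  dataset shift `beta_true`, and its sequencing platform observes
  exactly `alpha_true ×` the array value (defaults 1.15 and 0.35).
  This zero-intercept within-cohort relation is what makes the
  two-step fitting recipe exact on noise-free data; the composite
  reference-to-sequencing map is then `alpha·(e + beta)` rather than
  `alpha·e + beta`, and the constant difference `beta·(alpha − 1)`
  (≈ 0.05 log2 at defaults) sits far inside the 2-fold filter band.
  Non-conserved genes (20 % by default) get independent means per
  platform, offset by at least 1.5 log2 units, so the filter always has
  guaranteed true negatives. Panels can shift their mean rates; those
  shifts are panel-level offsets invisible to expression, so recovery
  claims use zero-shift cohorts.
* **Toy metabolic models.** A ~20-column (after splitting) network with
  two uptake exchanges, a glycolysis-like chain, a longer
  pentose-shunt-like alternative, two amino-acid routes of different
  lengths, a lipid chain, a biomass reaction draining three precursors,
  and a detox tail. Panel variants remove whole pathway blocks; with
  the default three panels, the shunt is present in exactly one panel's
  model and carries flux only there, giving the specificity and
  enrichment stages a known positive. Route lengths are strictly
  different so every variant has a unique pFBA optimum.

The generators deliberately omit probe-level array artifacts, count
noise of sequencing, gene–gene correlation structure, and any realistic
pathway topology. Passing tests therefore demonstrate that the
implementation recovers what the stated generative models plant — not
that the method would achieve comparable accuracy on real cohorts,
where conserved-gene filtering, platform corrections and metabolic
reconstructions are all approximate.

## Numerical choices and degenerate inputs

* Problem sizes in the test and acceptance runs: 500-gene universes,
  57-line panels, 45-sample three-panel cohorts, 100 enrichment
  permutations, 200-repeat null calibrations — sizes at which every
  stage's behavior is unambiguous and each full pipeline run completes
  in well under a minute.
* The simplex tolerance is 1e-10; feasibility is asserted as
  $\|S v\|_\infty < 10^{-7}$ and $|v_p - r_p| < 10^{-9}$ on every
  solved sample.
* Ties at exactly `max_dist` fail the conserved-gene filter (strict
  "less than").
* An empty passing set from the filter, all-negative predicted rates,
  or a single-panel flux matrix are reported as explicit errors or
  flagged empty results, never silent.
* Every stochastic step (fold assignment, permutations, generators)
  takes an explicit integer seed; identical seeds give bit-identical
  results, which the pipeline uses to guarantee byte-identical reruns.

## Known limitations

* The fixed-feature LOOCV mode inherits the mild optimism of full-data
  feature selection; use `mode = "nested"` for unbiased estimates.
* `boot::simplex` is a dense tableau implementation: fine for networks
  of tens of reactions, unsuitable for genome-scale models. The module
  boundary (an `irreversible_model` with a stoichiometric matrix) is
  where a sparse LP backend would plug in.
* NES values are unstable when the permutation-mean ES is near zero;
  such pathways are reported as undefined rather than given a spurious
  score.
* The specificity score compares means only; heterogeneity within a
  panel is invisible to it.
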