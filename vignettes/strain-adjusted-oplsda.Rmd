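---
title: "Strain-adjusted OPLS-DA for diet effects in multi-strain metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-adjusted OPLS-DA for diet effects in multi-strain metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabgxe)
```

## The problem

In a metabolomics study run across a panel of genetically divergent inbred
strains — for example Collaborative Cross (CC) mice crossed with a
vitamin-D-sufficient (VDS) versus vitamin-D-deficient (VDD) diet — the strain
main effects on metabolite concentrations are typically much larger than the
treatment effect of interest. A discriminant model supervised directly on
diet must then separate classes across a background of between-strain
variation it has no way to attribute, and real diet effects can be masked
entirely. `metabgxe` implements a pipeline built for exactly this design:

1. **Preprocessing** in the style used for untargeted (Metabolon-type)
   panels: per-run-day median normalization, per-metabolite rescaling to
   unit median, minimum-value imputation of below-LOD dropouts.
2. **Strain residualization**: per metabolite, an ordinary least squares fit
   of `metabolite ~ diet + strain` with treatment coding; the estimated
   strain coefficients are subtracted from the data, the diet term is left
   in.
3. **OPLS-DA** on the corrected matrix, supervised by diet, with
   cross-validated Q2 and a label-permutation test for significance.
4. **Feature selection** by VIP scores, combined with a symmetric
   fold-change filter, followed by strain-stratified univariate statistics
   and hypergeometric set enrichment.

A synthetic-data generator reproduces the statistical structure of the
target design so every stage can be exercised against a known ground truth.

## Preprocessing model

Run-day (instrument batch) effects are treated as multiplicative and
constant within a day: each metabolite's values are divided by the
metabolite's within-day median, which makes the step *exactly* invariant to
arbitrary per-day scale factors. Rescaling each metabolite to overall unit
median puts compounds with very different numerical ranges on a comparable
scale so that no compound dominates the multivariate model purely through
its units. Both steps use the standard median convention (mean of the two
central order statistics for even counts). Degenerate blocks — a
(metabolite, day) block with no observed values, or a zero median — raise an
error naming the offending block rather than propagating division by zero.

Missingness is interpreted as left-censoring at the limit of detection, and
each missing cell is filled with the minimum *observed* value of that
metabolite. Imputation runs after normalization and rescaling, and never
introduces a value below the observed column minimum. The `imputed` mask on
the returned object records exactly which cells were filled.

## Strain residualization

For each metabolite independently, the additive model
`value ~ diet + strain` is fitted by OLS with reference levels VDS (diet)
and a user-chosen baseline strain (default `CC011`). Each sample's
estimated strain coefficient is subtracted from its value; baseline-strain
samples are left bit-identical. Two algebraic identities follow from the
projection structure and are asserted in the tests: refitting the same
model on corrected data returns strain coefficients that are zero to
numerical precision (hence the correction is idempotent), and the diet
coefficient is unchanged by the correction, in balanced and unbalanced
designs alike.

The model is deliberately additive: strain-by-diet interactions are *not*
removed, because strain-specific diet responses are part of the diet signal
the downstream OPLS-DA is meant to find. Note also that the correction is
additive on the preprocessed scale while biological effects are closer to
multiplicative; residual strain structure therefore survives the correction
(heteroskedasticity, interaction terms). That residual structure is exactly
what the orthogonal component of the OPLS-DA is there to absorb. An
optional natural-log transform (`log_transform` in `pipeline_config()`) is
available; it is off by default.

## OPLS-DA

`fit_oplsda()` implements the standard orthogonal-projections formulation
with NIPALS components. After centering, scaling (unit variance by default;
Pareto and center-only are options) and encoding the class as a centered
±1 vector `y`, each orthogonal component is extracted as:

- `w = X'y / ||X'y||`, `t = Xw`, `p = X't / t't`;
- `w_o ∝ p − (w'p) w`, normalized; `t_o = X w_o`; `p_o = X't_o / t_o't_o`;
- deflation `X ← X − t_o p_o'`.

One predictive component `(w, t, p, q)` is then fitted on the deflated
matrix. By construction every orthogonal score vector is orthogonal to the
centered class vector (asserted to 1e−8 in the tests), and with zero
orthogonal components the model collapses to one-component PLS1-DA — the
test suite verifies prediction equality to 1e−10 against an independently
coded PLS oracle.

**Cross-validation.** Q2 is computed by K-fold cross-validation (default
K = 7, folds stratified by class and drawn from the seed). Each training
fold re-estimates centering and scaling; held-out samples are passed
through the training fold's orthogonal filter before prediction.
Q2 = 1 − PRESS/TSS with TSS taken on the full centered class vector. On
training data R2Y is non-decreasing in the number of orthogonal components
and Q2 never exceeds R2Y.

**Permutation significance.** `permutation_test()` refits the full model —
including cross-validation — under uniform label permutations and reports
`pQ2 = (1 + #{Q2_perm ≥ Q2_obs}) / (1 + n_perm)` (add-one counting, so a
p-value of exactly zero is impossible; with the default 1000 permutations
the smallest attainable value is ≈ 0.001). The CV partition is drawn once
per test and reused across permutations: only the labels vary, which keeps
the comparison between observed and permuted fits exact and lets fold-wise
scalings be precomputed. Under the null the resulting p-values are
super-uniform at resolution `(k+1)/(n_perm+1)`.

**VIP scores.** With a single predictive component the predictive VIP
reduces to `sqrt(p) · |w_j|`; the orthogonal VIP averages squared
normalized orthogonal weights with per-component explained-X-variance
weights. Both tables have mean square exactly 1 across variables. The
combined measure `rmsVIP = sqrt((VIP_pred² + VIP_ortho²)/2)` is used for
selection in diet models (threshold 1.5, inclusive); one-vs-rest strain
signature models select on the predictive VIP alone, since there the
orthogonal part is by construction uninformative about the supervising
strain. The exact VIP algorithm of commercial OPLS-DA software is
proprietary, so the package follows the published open convention and
documents it; numerical equality with other implementations is not claimed.

A practical consequence of selecting on rmsVIP deserves emphasis: a
metabolite can carry a large *orthogonal* VIP purely because it is loaded
on structured within-class variation (for example imperfectly removed
strain effects) while having no diet effect at all. rmsVIP selection is
therefore paired with the symmetric fold-change filter
(`robust_change_filter()`, `max(FC, 1/FC) ≥ 1.5`) to control false
discoveries — the combined filter is the pipeline's robust selection, and
it is the combination, not the VIP threshold alone, that the recovery tests
hold to a false-discovery bound.

## Stratified statistics

Fold changes are ratios of arithmetic group means (VDD/VDS), per strain or
population-wide; a non-positive denominator flags the ratio as undefined
rather than silently dropping it. Per-sample percentage change relative to
the within-strain VDS mean (`pct_reduction_25ohd()`) follows the
`(VDD_sample − VDS_mean)/VDS_mean` convention; by linearity the mean of the
per-sample values equals the change of the group mean, which the tests
assert exactly.

The univariate battery mirrors the classical gated workflow: per-group
Shapiro–Wilk at α = 0.05 decides parametric vs rank tests (Wilcoxon /
Kruskal–Wallis); Bartlett's test then decides pooled vs Welch forms of the
t test / ANOVA. Groups too small or constant fall back to the rank branch
with a warning; identical data return p = 1. The Brown–Mood median test
classifies observations against the grand median and tests the resulting
table (Fisher's exact test when any expected count is below 5). The
Tukey–Kramer HSD uses the studentized-range distribution with Kramer's
unequal-n correction (via `aov` + `TukeyHSD`), and the compact letter
display is assigned by insert-and-absorb so that two groups share a letter
exactly when not significantly different. Raw p-values are read at
α = 0.05 as in the classical workflow; Benjamini–Hochberg adjusted columns
are emitted alongside, labelled as an extension.

## Enrichment

`ora()` performs one-sided hypergeometric over-representation of the
selected metabolites against user-supplied (GMT) sets. The universe is the
set of metabolites present after preprocessing — not the whole set
database — matching the matched-universe behavior of the common web tools.
Sets are intersected with the universe first; sets smaller than 2 after
intersection are skipped so untestable sets do not dilute the BH FDR.

## The synthetic generator

`simulate_study()` emulates the target design: 8 CC strains × 2 diets,
72 dams in groups of 3–6 (drawn uniformly, then nudged to the exact total;
explicit group sizes can be supplied), 654 metabolites, 4 run days assigned
round-robin so every batch contains every group and the day medians stay
estimable. Effects are additive on the natural-log scale and exponentiated:

- baselines `N(0, 1)`;
- strain shifts on a 30% subset of metabolites, `N(0, 0.5)` per
  (strain, metabolite), centered within metabolite — about ±65% CV between
  strains, in line with the several-fold strain differences such panels
  show;
- diet effects on 78 metabolites with |log2 FC| drawn uniformly from
  [1, 2] and positive sign with probability 0.75 — anchored to the
  "predominantly upregulated, at least 2-fold" character of a detectable
  diet response at this sample size;
- strain-specific responder effects that *pin* the named strain's total
  fold change on a labelled responsive subset (defaults: one strain at
  4.5-fold on the fatty-acid subset, another at 9-fold on the
  glycerophospholipid subset), with the interaction term absorbing the
  difference from the population effect;
- run-day factors `N(0, 0.1)` on the log scale, residual noise with
  CV 0.3, and per-metabolite censoring of the lowest 2% of values to
  missing.

All randomness fans out from a single seed into per-component substreams,
so the full study — including the censoring pattern — is bit-reproducible.
The generator writes its injected effects into a `SyntheticTruth` record
used by the recovery tests.

What the generator does *not* emulate: correlated metabolite modules
(covariance between metabolites beyond shared design effects), platform
differences between LC-MS runs, drift within a day, missingness that is not
left-censoring, and litter-level covariance. Passing recovery tests
therefore demonstrate correctness of the estimation machinery under the
declared model, not robustness to every failure mode of real data. Because
detectability at 72 samples requires effects of at least about 2-fold, the
generator's diet signal is deliberately stronger relative to the strain
background than in a typical real panel; in particular the masking
phenomenon (a diet effect invisible before strain adjustment) is only
partial here, and with these defaults the unadjusted model is usually also
significant. The adjustment step is validated by its algebraic identities
and by recovery, not by reproducing masking.

## Numerical choices and scales

- Median convention: mean of central order statistics; zero or missing
  medians are hard errors.
- Constant columns pass through scaling untouched (scale factor 1).
- Class encoding ±1 centered by the class mean; the second factor level is
  +1. Ties are broken by first-index order throughout.
- `k_ortho` defaults to 1; `"auto"` adds components while CV Q2 improves by
  more than 0.01. Requesting more components than the orthogonal rank of X
  is an error.
- Add-one permutation counting avoids p = 0; permutation vectors are
  returned for inspection.
- Default problem sizes in the test-suite Monte-Carlo checks (chosen to
  make sampling error small relative to the asserted margins while keeping
  the suite quick): 20 random instances for oracle equivalence, 200 null
  datasets of 40 × 100 at 99 permutations for calibration, 25 study-scale
  replicates (72 × 654) for end-to-end recovery.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(n_perm = 1000, seed = 1)
res <- run_report(cfg, out_dir = "report")
res$summary
```

The summary reports the cross-validated Q2 and its permutation p-value, the
number of rmsVIP-selected and robust (VIP + fold-change) metabolites, and
the number of significantly enriched sets against the simulated
positive-control pathway collection. The same numbers are written to
`report/summary.json`, and every table in the output directory carries the
seed and a configuration hash in its header comments, so a rerun with the
same pair reproduces the numeric tables byte for byte.

## Limitations

- Binary classes only; multi-strain structure is explored through PCA and
  one-vs-rest signature models, not a multiclass OPLS-DA.
- Per-metabolite independent fits with no shrinkage across metabolites, by
  design; with very small groups the univariate battery has little power
  and the Shapiro–Wilk gate itself is weak.
- VIP conventions differ across OPLS-DA implementations; selections made
  with a threshold of 1.5 are comparable within this package, not across
  software.
- The hypergeometric ORA treats metabolites as exchangeable; correlation
  between metabolites in the same set makes the nominal p-values
  anti-conservative, as for any ORA.
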