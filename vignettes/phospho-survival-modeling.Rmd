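---
title: "Modeling castration-resistant survival from phosphoprotein signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling castration-resistant survival from phosphoprotein signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalpls)
```

## The scientific question

Prostate cancer cell lines differ widely in their ability to grow in
androgen-depleted conditions, and that phenotype is not attributable to a
single pathway: MAPK/ERK, PI3K/AKT/mTOR and stress-kinase signaling all
contribute, they cross-talk, and their readouts (site-specific protein
phosphorylation) are strongly collinear. `signalpls` implements the
data-driven route to this problem: measure a panel of phosphoproteins per
(cell line, treatment, time point) by sandwich ELISA, measure relative cell
survival per condition by a viability assay, and ask how much of the
survival variation a linear latent-variable model of the phosphoproteome
explains, which proteins carry the weight, and which correlations between
readouts are robust to multiple testing.

## The regression model

The design matrix `X` has one row per treatment condition and one column
per (phosphoprotein, time point); with 8 proteins and 3 collection times
that is 24 columns against typically 18 conditions (3 cell lines × 6
treatments), so ordinary regression is underdetermined and partial least
squares is the field's standard tool. Both `X` and the survival vector `y`
are autoscaled (mean 0, variance 1 per column; `autoscale()`); the SIMPLS
algorithm (`fit_simpls()`) then extracts latent variables that maximize
covariance with the scaled response, deflating the cross-product vector
against an orthonormalized basis of the X-loadings so score vectors stay
orthogonal. We implement SIMPLS from scratch for the univariate-response
case; its correctness is pinned by two independent oracles in the test
suite (equality with ordinary least squares at full rank, and with a
hand-coded NIPALS-PLS1 implementation at every component count).

Key parameters, defaults, and why:

* **Components `ncomp = 3`** — with low-rank signaling structure,
  additional latent variables beyond three add little; three is the
  standard choice for panels of this size and is used everywhere in the
  package's defaults.
* **R² convention `r2_method = "corr2"`** — the squared Pearson correlation
  between measured and cross-validated predicted survival. A permutation
  null of a squared correlation has a positive mean, which matches how
  randomized-model baselines are usually reported for this statistic; the
  `one_minus_ss` convention (which goes negative for models worse than the
  mean) is available everywhere, because published cross-validated R²
  values often do not state their convention.
* **Cross-validation `scaling_mode = "per-fold"`** — scaling parameters are
  re-estimated inside every leave-one-out fold so the held-out condition
  never leaks into the model; a `"global"` mode (scale once, then leave
  out) is provided because some published pipelines scaled before the
  leave-one-out loop. The no-leakage property is asserted in the tests by
  corrupting a held-out condition's survival and checking its out-of-fold
  prediction is bit-identical.
* **SD convention `sd_type = "sample"`** — the n−1 divisor, the common
  autoscaling convention; the choice cancels in correlation-based R², and
  a population-SD mode exists for exact comparison against pipelines that
  used it.
* **Permutations `n_perm = 3000`** — whole rows of `X` are shuffled against
  fixed `y` (never within columns, which would destroy the
  within-condition covariance the null should preserve). The z-score and
  one-tailed normal p-value follow the normal approximation to the null;
  because 3000 replicates cannot resolve tail probabilities below ~3e-4,
  the empirical exceedance fraction is always reported next to the normal
  p as a distribution-free cross-check.

## Ranking, incremental models, error grouping

Protein importance is the mean of |coefficient| over the protein's time
columns (`mean_abs_coefficients()`), ranked descending with ties broken by
declared protein order. One caveat the synthetic experiments make visible:
PLS coefficients spread weight across collinear columns, so proteins whose
trajectories share a signaling module with a genuinely predictive protein
inherit part of its coefficient mass. Top-of-ranking identity is robust;
the precise order further down is not, and should be read jointly with the
incremental curve. `incremental_r2()` refits on the cumulative column sets
of the ranking, so the step heights show how much information each protein
adds beyond those before it; the final step is by construction the full
model. `prediction_error_summary()` groups out-of-fold absolute percent
errors by treatment, cell line or inhibitor and compares groups with
two-sided Welch tests (reported unadjusted, with BH-adjusted values
alongside; with a handful of groups the unadjusted values are what is
conventionally quoted, and the adjusted column makes the multiple-testing
cost explicit).

## Correlation networks and response graphs

`pairwise_correlations()` correlates every unordered pair of proteins over
the concatenated (condition × time) observation vector — by default the
untreated control plus the six ligand treatments at all three times, 21
observations — with exact t-transform p-values. Inhibitor-combination
conditions are excluded from correlation analysis: co-variation under
targeted kinase inhibition answers a different question than ligand-driven
co-variation. Multiple testing uses Storey q-values
(`storey_qvalues()`): π₀ is estimated at a fixed λ = 0.5 and clamped into
(0, 1]; with π₀ = 1 the procedure reduces *exactly* to Benjamini–Hochberg,
which is the oracle the tests pin it against. The q-value family is the 28
pairs of one cell line, matching how per-cell-line q-values are reported in
this field; since the original Storey software's smoother-based π₀ is
version-dependent, fixed-λ values are expected to agree approximately, not
bit-for-bit, with that tool. Significance tags follow network-figure
conventions: `q_significant` (solid edge), `p_only` (dotted), `none`.

Response graphs (`build_response_graph()`) connect each ligand (or
inhibitor) to each protein with weight equal to the mean percent change
over control across the three time points; negative weights (reductions,
drawn red/dashed in figures) carry sign −1, and `split_response_graph()`
separates reduction from activation edges as inhibitor figures
conventionally do. Percent change — not raw concentration — is used *only*
here; the regression itself uses concentrations, because the model's
columns are phosphorylation levels, and percent change would discard the
between-cell-line level differences the model needs. Exports are GraphML
(with `weight`, `sign`, `abs_weight` attributes) or SIF plus a TSV
edge-attribute table, both loadable by Cytoscape.

## Heatmap clustering

`zscore_matrix()` + `hierarchical_order()` prepare the conventional
z-scored heatmap with agglomerative clustering on Euclidean distances.
Average linkage is the default (the common choice for omics heatmaps;
complete and single linkage are options, since the linkage used for
published figures of this kind is typically unstated). Items are pre-sorted
by label before clustering, which makes the dendrogram deterministic and
invariant to input row order. Exact reproduction of any particular
published heatmap ordering is explicitly not a goal; the property the
package tests is qualitative — conditions cluster by cell line before
treatment when between-line differences dominate.

## The synthetic-data generator

`synthetic_spec()` describes a study: 3 cell lines × (untreated control +
6 ligand/drug treatments), 5 inhibitors × 6 treatments on one designated
line, 8 phosphoproteins × {0.5, 4, 24} h, biological duplicates. The
generative model is:

* **Measurements.** `value = baseline × max(1 + F·L, rel_floor) ×
  log-normal noise`. `F` holds per-condition activities of `latent_rank`
  (default 3) signaling *modules*; `L` is a deterministic loading matrix:
  proteins are assigned round-robin to modules, the first protein of each
  module is its flagship (loading 1, co-members 0.6/0.45/…), and each
  module follows an early-, late- or mid-peaking time profile. Cell lines
  differ by fixed shifts of module activity (scale `cell_shift = 2.5`),
  inhibitors suppress their target module by 1.5 SD, and untreated
  controls sit exactly at baseline. Multiplying — rather than
  exponentiating — the latent effect keeps the centered measurement matrix
  exactly rank `latent_rank` in the noise-free limit, so a 3-component
  model can represent the planted map exactly; positivity is preserved by
  the relative-effect floor and by making all noise multiplicative
  log-normal.
* **Duplicates.** Two log-normal draws around the condition mean, with
  log-SD `replicate_cv × √π/2` — the half-normal relation under which the
  mean absolute relative difference between duplicates converges to
  `replicate_cv` (default 0.204, i.e. ~20% replicate error, typical for
  phospho-ELISA duplicates). The stored `value` is the duplicate mean.
* **Survival.** `100 × (1 + X_s β + ε)` for treated conditions, computed
  from the *stored* (duplicate-averaged, noisy) values after column
  scaling, so survival is exactly linear in the data a user sees; controls
  are 100% by definition, and a floor (default 1%) guards against negative
  viability. The default β plants 0.12/0.05/−0.035 per time column on
  Erk/RPS6/JNK — one clearly dominant protein, survival SD ≈ 30% of
  control, and essentially no floor clipping.
* **Seeding.** One global seed expands through `stage_seed()` into named
  substreams (synthesis, permutation, …), so changing the number of
  permutations never perturbs the generated dataset, and a fixed seed fixes
  everything bit-for-bit.

`signal_fraction()` is the generator's analytic reference for model
quality: the planted signal decomposes into a part carried by the low-rank
condition-level structure and a part borne by measurement/replicate noise
in the stored values; only the former is attributable by a low-rank model,
so the reference is `var(structured signal) / (var(total signal) +
noise_sd_y²)`. At the defaults, the pipeline's leave-one-out R² tracks this
fraction to within a few hundredths (the residual gap is leave-one-out
shrinkage at n = 18).

What the generator deliberately does **not** emulate: the extreme dynamic
range of real phospho-responses (three-order-of-magnitude spikes such as a
3200% activation are legal inputs but not generated at defaults), assay
floor/saturation artefacts, plate and batch effects, missing blocks, and
any mechanistic kinetics — it is a statistical emulator, so passing tests
demonstrate correctness of the *pipeline*, not biological fidelity of any
particular inference on real data.

## Numerical choices and degenerate inputs

* SIMPLS stops extracting components early (with a warning) when the
  residual covariance norm falls below 1e-12 of its initial value, and the
  loading basis is re-orthogonalized each step to limit drift.
* `fit_simpls()` refuses uncentered input (|column mean| > 1e-6) rather
  than silently centering: centering choices interact with
  cross-validation and must stay explicit.
* Zero-variance columns are centered and divided by 1 (with a message)
  instead of producing NaN; zero-variance response is a hard error in
  correlation-based R².
* Standard curves are quadratic in concentration (absorbance =
  a·c² + b·c + d), the orientation that matches comparing a measured
  absorbance back to the curve; fits that are non-monotone over the
  standard's range are rejected outright so the analytic inverse is unique.
  Derivative-at-endpoint zeros are tolerated to numerical tolerance.
* Incomplete condition blocks are rejected, never imputed.
* Welch comparisons that are undefined (zero-variance groups) return NA
  rather than failing the whole summary.

## Problem sizes used by the test and acceptance runs

The shipped tests exercise the study-sized design (18 × 24 main model,
36-row inhibitor model), 100 replicate studies for ranking/signal-fraction
recovery, 200 null datasets for permutation calibration, and 3000
permutations in the acceptance script — sizes chosen to estimate the
Monte-Carlo quantities they check to well within the asserted tolerances.

## Known limitations

* Univariate response only; no multi-response PLS, kernel/OPLS variants, or
  automatic component selection.
* The permutation p-value leans on the normal approximation, as is
  conventional for this statistic; the empirical exceedance is the
  distribution-free fallback and is reported everywhere.
* Per-cell-line models (6 conditions each) report training fit R², flagged
  as such — leave-one-out with n = 6 would be too unstable to be
  meaningful.
* Coefficient rankings below the top positions are sensitive to
  collinearity, as discussed above.
* π₀ estimation uses a single fixed λ; the bootstrap/smoother estimators of
  dedicated q-value software will differ slightly in small families.
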