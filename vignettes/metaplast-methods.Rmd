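---
title: "Models and methods behind metaplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaplast)
```

`metaplast` analyses replicated multi-environment metabolite panels of
crop varieties: long tables keyed by (variety, environment, block,
compound), where an environment is a location-by-year combination. This
vignette explains the statistical machinery, the defaults and why they
were chosen, what the synthetic-data generator does and does not
emulate, and the numerical conventions used throughout.

## The generating model and the synthetic panels

The generator (`sim_spec()` / `simulate_panel()`) draws

$$y_{vebc} = \mu_c + g_{vc} + h_{ec} + (gh)_{vec} + b_{eb} + \varepsilon_{vebc},$$

with variety main effects $g$, environment main effects $h$, a
variety-by-environment interaction $(gh)$, block-within-environment
effects shared by all compounds, and i.i.d. residual noise. Under the
lognormal model the observation is $\exp(\cdot)$ of that sum, which
keeps abundances strictly positive — the natural choice when a
Bray–Curtis analysis or the presence-filtered plasticity screen is the
target. The gaussian model is retained because it admits exact
closed-form checks (a zero-noise panel reproduces the model values to
machine precision).

Identifiability conventions: $g$ and $h$ are centred to sum to zero and
the interaction matrix is doubly centred per compound. Three interaction
regimes are available: unstructured gaussian noise; a rank-$r$ product
of centred unit vectors scaled so its root-mean-square equals
$\sigma_{g\times e}$ (the regime an AMMI fit recovers exactly when
residual noise is off); and a regression regime
$(gh)_{vec} = (\beta_{vc}-1)h_{ec}$ in which the Finlay–Wilkinson slope
of variety $v$ equals $\beta_{vc}$ by construction. The last identity is
exact only when the slopes average to 1 across varieties — the
environmental index is the variety mean, so a common factor in the
$\beta$'s is absorbed into the index; the constructor warns rather than
errors when $\bar\beta \ne 1$, because deliberately unbalanced slope
sets are occasionally useful.

Reproducibility: one master seed drives the block effects; every
compound then gets its own generator sub-stream keyed by a deterministic
31-bit hash of (seed, compound name). Adding or removing a compound
therefore never perturbs the values simulated for the others, which
keeps fixtures stable as scenarios grow.

Two ready-made designs mirror the two phases of a typical diversity
study: `sim_spec_diversity()` (16 varieties × 3 locations × 1 year ×
2 blocks × 86 compounds) and `sim_spec_plasticity()` (5 varieties ×
10 locations × 2 years × 3 blocks × 39 compounds). Per-compound
magnitudes are family conventions, not estimates: base levels between 4
and 50 (arbitrary family units) with relative components
$\sigma_e/\mu = 0.25$, $\sigma_g/\mu = 0.18$,
$\sigma_{g\times e}/\mu = 0.08$ and $\sigma_\varepsilon/\mu = 0.06$ —
an environment-dominated hierarchy typical of root-vegetable quality
panels. What the generator does **not** emulate: detection limits and
censoring, chromatographic measurement-error structure, and co-regulation
(correlation) between compounds. Tests passing on these panels therefore
validate the estimators' algebra and their behaviour under realistic
variance hierarchies, not robustness to those real-data artefacts.

## Variance partitioning

Profiles are centred and scaled per compound (sample sd, $n-1$), then a
Bray–Curtis dissimilarity matrix is built. Bray–Curtis is undefined on
negative values, so a `shift_policy` states how scaled data are made
non-negative: the default `minshift` translates each compound so its
minimum is zero; `range01` rescales to the unit interval; `raise`
refuses negative input. The choice is recorded in the pipeline manifest
because it genuinely changes the distances — there is no canonical
composition of z-scaling with Bray–Curtis, and users comparing runs
should hold it fixed.

The partition itself uses sequential (Type I) sums of squares in the
order environment, variety, interaction, with pseudo-F statistics and
free-permutation p-values carrying the +1 correction
$(1 + \#\{F^* \ge F\})/(1 + n_{perm})$; the default 9999 permutations
follow common practice for panels of ~100 samples. Computation is
delegated to `vegan::adonis2`; the wrapper seeds the permutations and
adds the mean-square–share column often quoted alongside such tables.
On balanced designs the Type I order is immaterial. With one factor and
Euclidean distances the pseudo-F reduces exactly to the classical
one-way ANOVA F, which the test suite uses as an oracle, and the type-I
error at $\alpha = 0.05$ is verified to be calibrated over 1000 null
simulations of 12 samples with 999 permutations each (sizes chosen to
keep the whole calibration run under a minute while leaving the binomial
confidence interval tight enough to detect miscalibration).

## The PC-area variability metric

With three environments, a variety's block-mean profiles project to
three points on the first three principal components; the area of that
triangle, $\tfrac12\lVert (L-A)\times(S-A)\rVert$, is a single
non-negative summary of how much the variety's whole profile moves
across environments. The PCA runs on block means (not individual
blocks), so replicate noise does not inflate the areas. Axis signs are
fixed deterministically (largest absolute loading positive); the area is
invariant to sign flips and rigid rotations and scales quadratically,
all asserted as properties.

The weighted variant multiplies axis $k$ by
$f_k / \bar f_{1:3}$, the inertia fraction normalized by the mean
fraction of the three components. Normalization keeps the weighted area
on the same scale as the raw one (mild inflation, identical ranking),
which matches how such tables are usually reported; raw-fraction
weighting is available via `weight_mode = "raw"`. The metric is defined
only for exactly three environments — with more, a triangle no longer
summarizes the cloud, and the environmental CV or the stability models
are the appropriate tools.

## The plasticity screen

Amplitudes are computed per compound on the variety × environment
block-mean matrix after z-scaling the whole matrix (mean 0, sd 1).
Scaling makes amplitudes comparable across compounds measured in
heterogeneous units (g/100 g sugars vs ppb volatiles); `scale_mode =
"raw"` is available for single-family analyses. Only compounds
accumulated by every variety in every environment (all means strictly
above `presence_threshold`, default 0) enter the screen, since a range
is meaningless around structural zeros.

The amplitude matrix is then treated like a contingency table:
$E_{vc} = S_{ci} S_{rj} / S_t$ from the margins, and
$r_{vc} = (A_{vc} - E_{vc})/\sqrt{E_{vc}}$. The margin-product
expectation says: "if variety $v$ is generally plastic and compound $c$
is generally labile, this is the amplitude you'd expect"; the residual
flags cells that break that factorization — a *differential* of
plasticity, which is exactly the G×E signal of interest. The
$\chi^2$-style residual is the default; the fully standardized form
(dividing by $\sqrt{(1-S_{ci}/S_t)(1-S_{rj}/S_t)}$) is available via
`adjusted = TRUE` since both conventions circulate under the name
"standardized Pearson residual". Compounds are ranked by
$\sum_v |r_{vc}|$ and selected when strictly above the median of those
sums; the strict inequality excludes the median compound itself, which
keeps the selected set just under half of the candidates and matches how
such screens are reported.

Power, verified by simulation: with five varieties in twenty
environments and a planted compound whose interaction sd is four times
the residual sd among interaction-free companions, the screen selects
the planted compound in more than 90% of 200 replicate panels.

## Stability models

All three classical models run per compound on the **raw-scale**
variety × environment block-mean matrix (sensitivity slopes are then in
content units per index unit, directly interpretable); matrices must be
complete — cells are never imputed, and incomplete matrices raise an
error naming the first missing cell.

* **Finlay–Wilkinson**: OLS of each variety on the environmental index
  $I_e$ (the variety mean per environment). Because the index is the
  row mean, slopes average exactly to 1, an identity asserted to 1e-9.
  Slope standard errors come from the per-variety regression residuals
  ($n-2$ df).
* **Ecovalence**: $W_v = \sum_e (y_{ve} - \bar y_{v\cdot} -
  \bar y_{\cdot e} + \bar y_{\cdot\cdot})^2$, summing exactly to the
  interaction SS of the two-way table.
* **AMMI**: SVD of the doubly centred table. $\sum_k \lambda_k^2$
  equals the interaction SS (hence $\sum_v W_v$), full-rank
  reconstruction reproduces the table to machine precision, and both are
  asserted. $K = 2$ axes are retained by default — the usual biplot
  choice — with all singular values always reported so users can judge
  the spectrum themselves; formal tests of $K$ are deliberately out of
  scope. Biplot scaling is symmetric ($\sqrt{\lambda}$ to both sides) by
  default, with environment- and genotype-focused scalings selectable,
  since conventions differ across the stability literature.

Numerical conventions shared by PCA and AMMI: axis signs are fixed by
making the largest-absolute-score element positive (environment side for
AMMI), so results are reproducible across LAPACK implementations;
rankings produced by `best_environments()` are invariant to those sign
choices, which is asserted.

## Pipeline, sizes and limitations

`run_pipeline()` chains the stages (ingest → block means → scaling →
PERMANOVA → PCA/areas/clustering/CV → screen → stability on the
selected compounds) and writes a manifest with the configuration, seed
and an MD5 of the canonical configuration JSON; identical configuration
and seed give byte-identical numeric outputs. Unknown configuration
keys are rejected outright — silent typos in an analysis configuration
are worse than an error. The random-forest marker screen is opt-in in
the pipeline (its label-permutation p-values refit the forest per
permutation, so the published-convention defaults of 500 trees and 2000
permutations are expensive; the test suite exercises it at reduced
sizes).

The test suite validates on deliberately small panels (4–6 varieties,
3–20 environments, 6–39 compounds; 25–1000 Monte-Carlo replicates),
chosen so the whole suite runs in well under a minute while leaving the
statistical checks (power, calibration, recovery) adequately powered.

Known limitations: no imputation for incomplete variety × environment
tables; no dispersion (PERMDISP-style) companion test for the
PERMANOVA; permutations are unrestricted (no blocking strata); the
triangle-area metric is restricted to three environments by
construction; and amplitude screening assumes compounds have been
quantified on a common within-compound scale across environments.
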