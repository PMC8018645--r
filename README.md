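# metaplast

Phenotypic-plasticity and stability analysis of multi-environment
metabolite panels.

## The problem

Breeding and quality programmes profile dozens of metabolites (sugars,
organic acids, carotenoids, terpenes, polyacetylenes, polyphenols, ...)
in a set of crop varieties grown at several locations and years, in
replicated blocks. Two questions drive the analysis:

1. **What shapes the metabolome** — how much of the variation in the
   whole profile is due to environment, to genotype, and to
   genotype-by-environment (G×E) interaction?
2. **Which compounds are plastic, and in which varieties** — which
   metabolites respond strongly to the environment, do varieties differ
   in that response, and which environments enhance accumulation for a
   given variety?

`metaplast` implements a complete pipeline for this design, together
with a synthetic-panel generator with known ground truth, so every
estimator can be validated by parameter recovery.

## Methods at a glance

* **Variance partitioning** — PERMANOVA on the Bray–Curtis
  dissimilarity matrix of centred/scaled profiles, sequential sums of
  squares over environment, variety and their interaction, free
  permutations (delegated to `vegan::adonis2`); `permanova()`,
  `bray_curtis()`, `partition_arithmetic()`.
* **Varietal variability in PC space** — for a variety grown in three
  environments with PCA scores A, L, S on the first three components,
  the triangle area ½‖(L−A)×(S−A)‖ (optionally inertia-weighted)
  summarizes how far its profile moves across environments;
  `pca()`, `pca_areas()`, `variety_area()`.
* **Static stability** — environmental coefficient of variation
  CV = 100·Sd/mean of a variety's block means across environments;
  `environmental_cv()`.
* **Plasticity screen** — per compound (z-scaled), the amplitude
  A(v,c) = max−min of variety v across environments; expected
  amplitudes from the margins, E = S_ci·S_rj/S_t, as in a contingency
  table; standardized Pearson residuals r = (A−E)/√E; compounds whose
  absolute-residual sum strictly exceeds the median are flagged as
  having a strong plasticity differential between varieties;
  `amplitudes()`, `expected_amplitudes()`, `screen_compounds()`.
* **Dynamic stability** — Finlay–Wilkinson joint regression of each
  variety on the environmental index (slope b_v, sensitivity); Wricke
  ecovalence W_v = Σ_e (y_ve − ȳ_v· − ȳ_·e + ȳ_··)²; AMMI
  decomposition y_ve = μ + g_v + h_e + Σ_k λ_k α_vk γ_ek + ρ_ve with
  biplot coordinates and per-variety environment rankings;
  `fw_regression()`, `ecovalence()`, `ammi()`, `best_environments()`.
* **Marker screen** — random-forest variety classification with
  Gini-importance permutation p-values (glue over `randomForest`);
  `marker_screen()`, `ward_clustering()`.

`run_pipeline()` orchestrates all stages from a long-format panel file
to a directory of CSV/JSON/Newick outputs plus a manifest;
`inst/scripts/run_pipeline.R` is a thin command-line wrapper.

## Worked example

```r
library(metaplast)

# 5 varieties x 20 environments (10 locations x 2 years) x 3 blocks,
# 39 compounds, seeded generator with ground-truth sidecar
sp  <- sim_spec_plasticity(seed = 42)
pan <- simulate_panel(sp)

A   <- amplitudes(pan$table)                 # z-scaled ranges
ea  <- expected_amplitudes(A)                # margins + Pearson residuals
scr <- screen_compounds(ea$residuals)
head(scr, 5)
#>    compound sum_abs mean_abs sd_abs selected
#> 17       S4   1.295    0.259 0.1499     TRUE
#> 26      T16   0.998    0.200 0.0587     TRUE
#> 30       T4   0.936    0.187 0.1932     TRUE
#> 19       S6   0.866    0.173 0.1472     TRUE
#> 4     FaDOH   0.817    0.163 0.1621     TRUE

mm <- block_means(pan$table, compound = scr$compound[1])
fw_regression(mm)
#> Finlay-Wilkinson joint regression: 5 varieties, 20 environments
#>   variety intercept slope slope_se resid_sd
#> 1     V01     0.526 1.103    0.123     2.54
#> 2     V02     1.382 0.869    0.113     2.34
#> 3     V03     0.934 1.015    0.118     2.44
#> 4     V04   -10.208 1.092    0.136     2.82
#> 5     V05     7.365 0.920    0.121     2.51

am <- ammi(mm, K = 2)
head(best_environments(am, "V01"), 3)
#>   environment predicted
#> 1      L07_Y2     40.29
#> 2      L05_Y2     40.27
#> 3      L02_Y1     39.67
```

The screen table ranks compounds by the summed absolute Pearson
residuals (`sum_abs`): a large value means the varieties disagree in how
plastic that compound is. Slopes above 1 (V01, V04) mark varieties
hypersensitive to the environment for the top compound; the AMMI ranking
lists the environments where a variety's accumulation is predicted to be
highest.

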