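# odordisc

Which perceptual properties of odors — and which odors — are rated
differently by people with a reduced sense of smell (hyposmia) than by
normosmic raters?  `odordisc` implements a complete two-arm analysis
pipeline for 1–5 grade odor-rating studies of the four-set design
(4 odor sets × 10 odors × 7 properties × 2 repeat ratings), plus a
chemoinformatics stage and a synthetic-cohort generator so that every
step is testable without clinical data.

The two arms are:

* **Unsupervised**: diagnosis-stratified mean rating profiles (an
  80 × 7 matrix: 40 odors × 2 diagnoses by 7 properties) are projected
  by PCA on centered, unscaled data; each odor's displacement between
  its normosmic and hyposmic projections on the PC1 × PC2 plane is
  measured, and computed **ABC analysis** of the displacements splits
  the odors into distinctive (set A), intermediate (B) and
  non-distinctive (C) groups.
* **Supervised**: Monte-Carlo cross-validated random forests
  (per run: a stratum-balanced 2/3 training draw, 1000 trees,
  mtry = round(0.5·√280) = 8, ≤ 7 nodes/tree) classify the olfactory
  diagnosis from the 146 × 280 sparse block-diagonal subject-by-rating
  matrix.  Per run, each feature's Gini importance and its training-set
  Wilcoxon −log(p) between diagnoses are recorded, averaged over runs,
  rank-transformed, and fused by the **rank product** (multiplication of
  ranks = logical AND).  ABC analysis of the rank products in both rank
  directions yields the most and the least diagnosis-relevant
  (odor, property) cells; held-out AUC-ROC with a permuted-label
  negative control validates that the ratings carry diagnosis signal.

The arms are **fused by intersection** into final distinctive /
non-distinctive odor sets, and those sets are characterized chemically
with **CATS2D pharmacophore-pair descriptors** (counts of L/A/D/N/P-typed
atom pairs at topological distances 0–8; 10 pair types × 9 distances =
90 descriptors), a variance/correlation filter, and leave-one-out
tree-ensemble classification with a permutation control.

## Worked example

A full run on a synthetic cohort with the default planted effect
(hyposmic subjects rate familiarity and intensity one grade lower):

```r
library(odordisc)

cohort <- simulate_cohort(cohort_design(), effect_spec(shift = -1), seed = 7) |>
  filter_complete() |>
  impute_knn()

# unsupervised arm
proj <- project_profiles(build_mean_profiles(cohort))
glance(proj)
#>   n_profiles n_components retained_components retained_variance_fraction
#> 1         80            7                   2                      0.490
cats <- categorize_odors(paired_distances(proj))

# supervised arm
rel <- run_relevance(build_feature_matrix(cohort),
                     run_config(n_runs = 50, n_trees = 200, seed = 7))
rel
#> <relevance_result> 50 runs; median held-out AUC 0.982
sel <- rank_product_select(rel)
head(sel$property_tally$most, 3)
#>   property    n_cells
#> 1 intensity        37
#> 2 familiarity      36
#> 3 temperature       8

# consensus of the two arms
intersect_arms(exclusive_sets(sel), cats)
#> <consensus_result> 3 distinctive / 1 non-distinctive odors
#>   distinctive: 3-methyl-3-sulfanylhexan-1-ol, L-carvone, 2-methylpropanal
#>   non-distinctive: citronellol
#>   unsupervised confirmation: 75.0% / 100.0%
```

Reading the numbers: the forest separates the diagnoses almost perfectly
(median held-out AUC 0.982 versus ≈ 0.5 for `permuted_control()`), and
the two planted properties — intensity and familiarity — dominate the
most-relevant ABC set (37 and 36 of its cells; the next property holds
8).  With the shift planted on *all* odors the odor-level consensus is
arbitrary by construction; planting on an odor subset
(`effect_spec(affected_odors = ...)`) makes the final distinctive set a
recovery target, quantified by `planted_enrichment()`.

The chemoinformatics stage runs from the packaged 11-odorant panel
(structures curated from public databases):

```r
panel <- final_odorants()
desc  <- cats2d_matrix(panel)      # 11 molecules x 90 CATS2D counts
chem  <- loo_classify(filter_descriptors(desc), panel$label, seed = 1)
```

`autoplot()` methods draw the ABC curve, the PCA score plane and the
odor-by-property importance heat map; `tidy()`/`glance()` return result
tables as tibbles.

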