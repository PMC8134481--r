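---
title: "Methods: two-arm analysis of odor perceptual spaces in olfactory loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-arm analysis of odor perceptual spaces in olfactory loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odordisc)
```

## The scientific question

People with a reduced sense of smell (hyposmia) do not simply perceive
odors "less": different perceptual dimensions degrade differently.
Ratings of *familiarity* and *intensity* depend on intact olfactory
receptor input, while *painfulness*, *temperature* and *irritation* are
largely trigeminal (chemesthetic) and survive olfactory loss.  `odordisc`
implements a two-arm analysis that asks, from a table of 1--5 grade
ratings of odors on seven perceptual properties, **which properties and
which odors discriminate normosmic from hyposmic raters** -- and then asks
whether the discriminating odors share chemical structure, using CATS2D
pharmacophore-pair descriptors.

The rating design is fixed throughout: subjects are assigned to one of
four odor test sets of 10 odors; every odor is rated twice on each of
seven properties (edibility, intensity, irritation, temperature,
familiarity, hedonics, painfulness) with grades 1--5.  Because a subject
only rates their own set, the subject-by-rating matrix (146 subjects by
4 x 10 x 7 = 280 columns at the default design) is sparse
block-diagonal.

## Data preparation

* **Completeness filter** (`filter_complete()`): subjects keeping fewer
  than two thirds of their 140 required ratings are excluded.
* **kNN imputation** (`impute_knn()`, k = 3, within odor set): a missing
  rating slot is filled from the k most similar subjects of the same set.
  Similarity is the root-mean-square difference over mutually observed
  slots -- dividing by the overlap size keeps subjects with few shared
  slots from appearing spuriously close -- and the imputed value is the
  exp(-distance)-weighted mean of the neighbours' values for that slot.
  Observed values are never altered, so imputation of a complete cohort
  is the identity.  If fewer than k neighbours observe a slot, the
  within-set slot mean is used and a message is emitted.  Distances are
  computed on raw grades (the scale is common to all items, so
  standardization would only rescale a shared unit).
* **Matrices** (`build_feature_matrix()`, `build_mean_profiles()`):
  repeat ratings collapse by arithmetic mean; the feature matrix keeps
  out-of-block cells structurally absent (`NA`), and the mean-profile
  matrix averages grades per (odor, diagnosis) over subjects and
  repetitions, giving 80 rows by 7 properties.

## Computed ABC analysis

Both arms reduce "a vector of positive relevance values" to a small set
of items worth naming.  `abc_partition()` sorts the values in descending
order and builds the discrete cumulative curve of *effort* (fraction of
items) versus *yield* (fraction of the value sum), which runs from (0,0)
to (1,1) and is concave.  Set A ends at the curve point closest
(Euclidean) to the ideal point (0,1); set C begins after the break-even
point, the first item whose value falls below the mean (piecewise slope
< 1).  If break-even precedes the A|B point, B is empty.  The
construction is fully discrete -- no smoothing or interpolation -- so it
has no bandwidth parameter and is reproducible to the bit.  Ties keep
their input order; an all-equal vector is legal (it arises under
permutation controls) and is categorized by the same diagonal-curve
geometry.  Tests check the partition exhaustively against a brute-force
geometric oracle for every value list of length <= 8 over {1, 2, 3}.

A geometric consequence worth knowing: for value vectors without strong
concentration (e.g. products of roughly uniform ranks) the A|B point
settles near one third of the items.  This matches the three roughly
equal odor groups the displacement analysis produces, and it means set A
is only "few" when the input values are genuinely skewed.

## The unsupervised arm

`project_profiles()` centers (no scaling -- the seven properties share
one grade unit) the 80 x 7 mean-profile matrix and decomposes it with
`stats::prcomp`.  Components are sign-fixed deterministically (largest-
magnitude loading positive) so score tables reproduce across platforms.
Property *contributions* are squared loadings normalized per component
(x 100).  `paired_distances()` measures, per odor, the Euclidean
distance between its normosmic and hyposmic projections on the retained
plane (2 components by default; full-space distances are available via
the `components` argument).  `categorize_odors()` runs ABC analysis on
the distances: A = distinctive odors (largest displacement), C =
non-distinctive, B = intermediate.  Exact zero distances are nudged by
machine epsilon (with a message) because ABC analysis requires positive
input.

## The supervised arm

`run_relevance()` repeats, `n_runs` times (default 1000; tests and the
acceptance script use 60--100 with 200-tree forests to keep runtimes in
minutes):

1. a **stratified Monte-Carlo split**: training subjects are drawn
   without replacement from every diagnosis-by-set stratum.  By default
   the *same number* -- `round(2/3 x smallest stratum)` -- is drawn from
   every stratum (`balance = "balanced"`).  This matters: the default
   cohort has unequal hyposmic prevalence across sets (8/38, 9/33,
   17/42, 8/33), and since the forest can recognize a subject's set from
   the block pattern, proportional sampling would let it score subjects
   by set prevalence alone (AUC ~ 0.60 with no signal at all).
   Balanced strata remove that shortcut, and the null control then sits
   at chance.  Proportional sampling remains available
   (`stratified_split(..., balance = "proportional")`).
2. a **random forest** (1000 trees by default, mtry =
   `round(0.5 * sqrt(280))` = 8, at most 7 terminal nodes per tree)
   classifying diagnosis, recording each feature's mean decrease in Gini
   impurity.  Out-of-block cells are encoded as the constant sentinel 0,
   outside the 1--5 grade scale, so splits on them only separate odor
   sets; `block_mode = "per_set"` instead fits one forest per odor set.
3. per-feature **Wilcoxon-Mann-Whitney tests** between diagnoses on the
   training subjects of the feature's own block (two-sided, normal
   approximation with tie correction), keeping -log(p).  Zero-variance
   features contribute p = 1.
4. **held-out AUC-ROC** on the remaining subjects (fixed direction:
   hyposmic scored high), via pROC.

Importance and -log(p) are averaged over runs and reshaped to
odor-by-property matrices.  `permuted_control()` repeats the whole loop
with labels shuffled before every run -- the negative control, expected
at chance.  `rank_product_select()` rank-transforms both matrices
(ascending, average ranks on ties) and multiplies them: a rank product
is large only if a cell is important to the forest AND shows a large
statistical group difference (a logical AND).  ABC set A of the products
gives the most relevant cells; inverting the ranks and repeating gives
the least relevant ones; cells claimed by both directions are dropped
from both.

## Consensus and enrichment

`exclusive_sets()` keeps odors appearing *only* among most-relevant
cells (or only among least-relevant), and `intersect_arms()` intersects
them with the unsupervised distinctive / non-distinctive categories.
The per-direction overlap fraction uses the supervised-exclusive set as
denominator.  For synthetic cohorts with effects planted on a known odor
subset, `planted_enrichment()` gives the one-sided hypergeometric
probability of the attained overlap between the final distinctive set
and the planted set.  Because final sets are small (an odor is dropped
from the exclusive set whenever any one of its seven cells falls in the
other direction's A set), single-cohort enrichment p-values are coarse;
the acceptance checks therefore combine five independent cohorts by
Fisher's method, with empty final sets entering as p = 1.

## The synthetic cohort generator

`simulate_cohort()` draws grades from a latent Gaussian model: each
(odor, property) item gets a baseline mean uniform on the central half
of the scale (2--4 for grades 1--5, so +-1 shifts rarely saturate); a
subject's latent rating adds the planted diagnosis shift (hyposmic
subjects, affected items only) and Gaussian noise (sd 1 grade), then is
rounded and clipped to the scale.  Missing ratings are placed uniformly
at random within each subject at the design's `missing_rate` (default
0.05, comfortably inside the study's completeness threshold; the
observed median completeness in the study it emulates was ~94%).  The
defaults reproduce the study conditions: 146 subjects over sets of
38/33/42/33 with 8/9/17/8 hyposmic, 10 odors per set, 7 properties, 2
ratings per item.  The default planted effect is the finding the
pipeline is meant to recover: familiarity and intensity rated one grade
lower by hyposmic subjects.

What the generator deliberately does **not** model: correlated rating
styles within subjects, cultural effects on familiarity/hedonics, odor-
specific trigeminal profiles, informative missingness, or TDI subscore
structure.  Passing tests therefore show that the pipeline recovers
planted mean shifts under exchangeable noise -- not that it would find
the same structure in clinical data, where effect geometry is richer and
relevance values are more skewed.

## Chemoinformatics stage

`parse_molecule()` converts SMILES to a molecular graph through
OpenBabel (ChemmineOB/ChemmineR) with explicit hydrogens.  The
pharmacophore typing rule table (see `assign_pharmacophore_types()`)
assigns L/A/D/N/P types; proprietary descriptor engines differ in these
rules' fine print, so the table is a declared dialect of the classic
CATS conventions.  `cats2d()` counts typed atom pairs at topological
distances 0--8; the default `pair_mode = "distinct"` enumerates the 10
unordered pairs of distinct types (5 x 4 / 2), giving 90 descriptors;
`"full"` adds the five same-type pairs (135).  The published
descriptor lists that motivated this stage name both a 10-pair formula
and a same-type descriptor, which cannot simultaneously hold; both modes
are provided rather than resolving the ambiguity.

`filter_descriptors()` drops columns with variance < 0.2 and then
greedily one member of each pair with |r| > 0.75 (the member with the
larger mean absolute correlation; ties break toward the later column).
`loo_classify()` evaluates a random forest or bagged CART by
leave-one-out cross-validation with a permutation control.  Per-tree
bootstraps are class-balanced (`strata`/`sampsize`): with 4 versus 7
molecules, leaving one out depletes its class in training and would
otherwise bias every vote toward the majority class, dragging the
permuted-label control well below 0.5.

The 11-odorant panel shipped in `final_odorants()` carries SMILES
curated from public structure databases; it is a fixture for exercising
the stage, and its two labels are not expected to be separable from
synthetic-free structure alone at n = 11.

## Numerical and design choices, in brief

* Imputed grades stay real-valued (means), they are not re-rounded.
* Rank ties: average ranks, keeping rank products symmetric.
* AUC confidence intervals: percentile over Monte-Carlo runs.
* Seed policy: one master seed spawns per-run seeds, so results are
  reproducible and runs could be parallelized without changing results.
* Problem sizes in tests/acceptance: 60--100 Monte-Carlo runs with
  200-tree forests, 50 LOO permutation cycles; these keep the full suite
  in minutes while leaving medians stable to ~0.02 AUC.

## Known limitations

* With planted effects of realistic size, rank products of the mostly
  unaffected cells are close to uniform, the ABC A sets in both rank
  directions cover about a third of all cells, and the exclusive odor
  sets (and hence the consensus finals) shrink to a handful of odors;
  replicated-cohort enrichment against a hypergeometric null is then
  under-powered at a 40-odor universe.  This mirrors the strong
  shrinkage the two-arm design produces on real data and is a property
  of the method, not of its implementation.
* The pharmacophore rule table is one defensible dialect; descriptor
  counts can differ from engines with other donor/acceptor conventions.
* The unsupervised arm's retained plane defaults to two components; on
  synthetic cohorts these explain less variance than on structured
  clinical profiles, and distances on the plane discard the rest.
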