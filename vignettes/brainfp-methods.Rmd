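---
title: "Connectome fingerprinting methods in brainfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome fingerprinting methods in brainfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainfp)
```

## The problem

Resting-state functional connectomes are individual enough to act as a
"fingerprint": the region-by-region correlation structure of one
person's BOLD signal matches their own connectome from another scan (or
another half of the same scan) better than anyone else's. `brainfp`
implements the full analysis chain built on this observation for a
case-control setting such as Parkinson's disease (PD) versus matched
controls: quantify identifiability, map *where* on the connectome the
fingerprint lives, test where its reliability differs between groups,
and use the group-difference subnetwork as a feature-selection mask for
predicting which patients respond to an intervention.

Because clinical imaging cohorts of this kind are rarely deposited, the
package ships a synthetic-cohort generator with planted ground truth,
so every inferential stage can be validated end to end: calibration
under the null, sensitivity under planted effects, and chance-level
behaviour of the classifier when outcomes are uncoupled.

## Split-half connectomes and identifiability

Each subject's parcellated time series (time x region) is split into a
first half ("test") and second half ("retest"; the first half receives
`floor(T/2)` samples — the convention is arbitrary but fixed), and a
Pearson correlation matrix is computed per half. The upper triangle
(row-major, i < j) of each matrix is vectorized; one shared edge index
is used by every stage so that test/retest vectors, reliability maps
and masks always align.

Edge vectors are optionally residualized: at every edge, ordinary least
squares removes age, sex, education years, disease duration and onset
age (the last two are identically zero for controls and are dropped as
constant columns). Residualization is fit per group and per half with
the same covariates, and residuals are not re-inflated with the
intercept — this is what drives the mean cross-subject similarity
toward zero. Whether to pool groups into one design is genuinely open;
`residualize_scope = "pooled"` is available, with `"per_group"` the
default because identifiability matrices are built per group.

The identifiability matrix `M` holds `M[s, i] = cor(test_s, retest_i)`.
From it:

* `I_self(s) = M[s, s]`, a subject's self-similarity;
* `I_others(s)` = the mean of the `2N - 2` off-diagonal entries in
  subject s's row and column;
* `I_diff` = mean(`I_self`) − mean(`I_others`);
* `I_diff-norm` = the pooled-SD standardized difference between the
  within set (the N diagonal entries) and the between set (the
  `N^2 − N` off-diagonal entries) — an effect size comparable across
  conditions;
* `SR`, the identification success rate: the percentage of subjects
  whose self-similarity strictly exceeds every competing cross-subject
  similarity.

For `SR` the match criterion compares the diagonal against both the row
and the column off-diagonals by default (`match_scope = "both"`), with
strict inequality and ties counting as failure; a row-only variant is
provided because the literature is not consistent about the comparison
set.

### Bootstrap inference

Uncertainty in `I_diff-norm` is assessed by resampling subjects with
replacement (1000 iterations by default) and recomputing the statistic
from the resampled subject-level `I_self` and `I_others` values. We
deliberately resample subject-level summaries rather than rows/columns
of `M`: resampling the submatrix puts a duplicated subject's
self-similarity into the off-diagonal set, which systematically
collapses the statistic (we measured point estimates of ~5 shrinking to
bootstrap means of ~0.6 under submatrix resampling at N = 23). Paired
comparisons (e.g. raw versus residualized data) apply identical index
draws to both matrices. The two-tailed empirical p-value is
`(1 + #{|draw − mean| >= |0 − mean|}) / (B + 1)`, which cannot be
exactly zero.

## Edgewise reliability and its group differences

Per-edge test-retest reliability is the one-way random-effects
intraclass correlation with k = 2 repeats,
`ICC(1,1) = (MS_B − MS_W) / (MS_B + MS_W)`, where `MS_B` is the
between-subject mean square (df N − 1) and `MS_W` the within-subject
mean square (df N). Negative values are retained: truncating them would
bias the downstream differential test. Edges whose 2N values are all
identical have undefined ICC and are stored as `NA` sentinels, excluded
from every summary. Estimates are stabilized by repeated subsampling
(default 100 draws of 80% of subjects without replacement, averaged).
Conventional interpretation bands (poor < 0.4, fair 0.4–0.59, good
0.6–0.74, excellent >= 0.75) are exposed via `icc_band()`.

Network-level profiles average the upper-triangle edges of each of the
7 canonical networks' diagonal blocks (VN, SMN, DAN, VAN, LN, FPN,
DMN); rank agreement between two profiles is the proportion of network
pairs in the same relative order, tested one-sidedly against shuffles
of the second ranking. Ranking ties are broken by the fixed canonical
network order.

Group differences are tested edgewise by label permutation: whole
subjects (their test and retest vectors together, preserving the
temporal pairing) are reassigned to groups at the original sizes, the
per-group ICC maps are recomputed, and the observed difference is
compared two-sidedly to the null differences. The pooled cohort is
internally sorted by subject id before drawing assignments so that the
p-values are invariant under swapping the two group arguments.
Benjamini–Hochberg adjustment is applied across all E edges jointly,
and edges with adjusted p below the threshold (default 0.01) are split
into two directional masks with their touched-ROI sets.

### The permutation floor and FDR, at desk scale

Empirical p-values use the plus-one correction, so the smallest
attainable p is `1 / (n_perm + 1)`. Under BH at level alpha across E
edges, an edge at the floor can only be declared significant if at
least `E / (alpha * (n_perm + 1))` edges reach the floor. This
interaction matters at small scale: with E = 1225 and 200 permutations
no edge can survive alpha = 0.01 regardless of effect size. The
package does not hide this — test configurations are sized so the
arithmetic is feasible (small atlases, 1000–2000 permutations, or a
larger alpha for smoke runs), and users running reduced permutation
counts should check this bound before interpreting an empty mask.

## Masked subnetworks and graph features

The direction-of-interest mask (edges more reliable in controls than
patients) is applied to each patient's residualized full-series FC
matrix. By default exactly the mask's edges are retained ("edge" mode;
an ROI-induced-subgraph mode exists because both readings of a "ROI
mask" appear in practice), weights are absolute FC (signed residual
correlations would break several measures; a positive-only mode is
available), and isolated nodes are dropped with a message. The control
analysis without any fingerprint information uses proportional
thresholding: keep the top `ceiling(density * E)` edges by |FC| over a
density grid (default 0.05–0.95 in 0.05 steps), ties at the cut broken
by edge index.

Eight weighted measures are computed per subject, two per topological
domain:

* centrality — mean node strength; mean eigenvector centrality
  (principal eigenvector of the weight matrix by power iteration,
  non-negative, unit L2 norm);
* integration — characteristic path length with edge length 1/weight,
  averaged over connected ordered pairs (with a warning when the graph
  is disconnected); mean first-passage time of the random walk,
  computed from the fundamental matrix on the largest connected
  component;
* segregation — Louvain modularity of the best partition (fixed
  community seed for determinism); mean participation coefficient
  against that same partition (the masked subgraph spans atlas
  networks, so the atlas partition would be the wrong reference);
* organization — weighted degree assortativity over edge endpoint
  strengths; the weighted rich-club curve summarized by its mean over
  the degree levels where it is defined (a `max` variant is exposed).

Nodal measures are averaged over nodes to give one scalar per subject;
the mean was chosen over the median for continuity in small graphs.
All eight are validated against independent oracles (Floyd–Warshall,
per-target absorbing-chain solves, dense eigendecomposition) and are
invariant under node relabeling.

## Response labeling and nested cross-validation

Patients are labeled responders when the relative motor-score
improvement `(baseline − follow-up) / baseline * 100` reaches the
clinically meaningful boundary, inclusively (default 15%).

Classification uses nested leave-one-out cross-validation: each subject
is held out once; features are standardized with training-fold
parameters only; hyperparameters are tuned by stratified inner 5-fold
grid search scored on accuracy (the inner fold count drops, with a
message, when a class has fewer members than folds). Because LOOCV
folds hold a single sample, accuracy, precision, recall, F1, ROC-AUC
and PR-AUC are computed on the pooled held-out predictions — the only
coherent choice. Six model families are supported (random forest,
gradient boosting, k-nearest neighbors, logistic regression, SVM,
decision tree) with small standard default grids; kNN includes an
inverse-distance-weighted variant so its scores stay continuous.
Tree-based families report mean-decrease-in-impurity importances
averaged over outer folds and normalized to sum to one.

Significance is assessed by rerunning the entire nested pipeline under
label permutations; one-sided p-values for accuracy, ROC-AUC and PR-AUC
are BH-corrected as a family of three. PR-AUC is the inferred third
family member; it is computed as average precision.

## What the synthetic cohort does and does not emulate

Each subject's signal is a latent factor mixture: a group-common
component (loadings shared within group), a subject-unique component
(the fingerprint, identical loadings in both scan halves) and white
noise, with variance shares `group_share`, `fingerprint_share` and the
remainder. Loading rows are unit-normalized so shares are exact per
region. Stability differences are planted by remixing the designated
group's subject-unique loading rows for the regions of a network block
between halves (`sqrt(1 − m)` old + `sqrt(m)` fresh, re-normalized), which
lowers test-retest reliability there while leaving expected
connectivity unchanged. Remixing a region's rows perturbs *every* edge
incident to it, so ground truth records both the block-internal
`true_differential_edges` and the full incident `affected_edges` set.
Covariates shift edges approximately linearly via fixed perturbation
directions on the subject loadings. Outcomes couple responder status to
each patient's realized mean |FC| over the affected subnetwork through
a rank rule that fixes the responder count at
`round(responder_fraction * n)`; with zero coupling, outcomes are pure
noise. Baseline motor scores are drawn near a typical moderate-stage PD
cohort (mean 37.8, SD 11.7) and follow-ups are constructed from the
intended percent change, keeping a margin around the responder boundary
so integer rounding cannot flip labels.

Default calibration (chosen once): 30 subject factors, 6 group factors,
unit noise. With `fingerprint_share = 0.5`, no group component and
T = 400, this yields mean self-similarity near 0.6, cross-subject
similarity near zero and a 100% success rate at N = 23 — the regime in
which fingerprinting studies report perfect identification. The default
responder fraction is 13/23; published cohorts are ambiguous between
10/23 and 13/23 and the generator simply exposes the fraction.

The generator does **not** emulate hemodynamic response shapes, head
motion, physiological noise, scanner drift, spatial autocorrelation of
the parcellation, or any preprocessing artifacts. Passing tests
therefore demonstrate the correctness and calibration of the
*statistical machinery* under a well-specified generative model — not
robustness to the messiness of real fMRI.

## Problem sizes used by the test suite

Tests run at deliberately reduced scale, chosen as the smallest sizes
at which each property is stable: identification and calibration at
N = 23, R = 100, T = 400; planted-difference recovery at N = 24 per
group, R = 30, T = 800, 2000 permutations with a strong fingerprint
share (0.85) and full remixing (magnitude 1) — the regime where the
floor/FDR arithmetic above admits sparse detections; classifier
calibration over repeated outcome draws with a single-configuration kNN
(99–180 permutations); and a full-pipeline smoke run at R = 50,
N = 10 + 10 with 200 permutations at alpha = 0.05. Full-scale runs
(R = 400, 1000 permutations with subsampled nulls) use the same code
paths.

## Known limitations

* The permutation null recomputes ICC per permuted group; with
  subsampling enabled inside the null this is the most faithful but
  slowest option (`use_subsample` in the pipeline config controls it).
* The rich-club scalar and the nodal-measure aggregation are
  single-number summaries of curves/vectors; alternatives (max, median,
  per-node exports) are exposed where reasonable but the defaults are a
  choice, not a canon.
* Bootstrap CIs for `I_diff-norm` are percentile intervals of the
  subject-level statistic; they are not bias-corrected.
* With very small cohorts (under ~8 per group) the residualization
  design can exhaust degrees of freedom; the functions fail loudly
  rather than silently dropping covariates beyond constant columns.
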