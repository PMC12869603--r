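# brainfp

Functional connectome fingerprinting and fingerprint-informed
prediction of treatment response, in R.

## What it does

A resting-state functional connectome — the matrix of Pearson
correlations between regional BOLD time series — is stable enough
within a person, and variable enough between people, to act as a
*fingerprint*. `brainfp` implements the analysis chain built on that
observation for case-control neuroimaging studies (e.g. Parkinson's
disease vs matched controls):

1. **Split-half connectomes** — each scan's time series is split in
   two; a test and a retest FC matrix per subject, vectorized on one
   shared edge index, optionally residualized against age, sex,
   education, disease duration and onset age.
2. **Identifiability** — the matrix `M[s, i] = cor(test_s, retest_i)`
   and its summary metrics:
   `I_self(s) = M[s,s]`,
   `I_others(s) = (Σ_{i≠s} M[s,i] + M[i,s]) / (2N − 2)`,
   `I_diff = mean(I_self) − mean(I_others)`, the pooled-SD standardized
   `I_diff-norm`, and the identification success rate `SR` (percentage
   of subjects whose self-similarity beats every competing entry), with
   subject-level bootstrap inference.
3. **Edgewise reliability** — per-edge one-way random-effects
   `ICC(1,1) = (MS_B − MS_W)/(MS_B + MS_W)` (k = 2 repeats), stabilized
   by repeated 80% subsampling, plus nodal strengths, 7-network
   profiles and a ranking-concordance permutation test.
4. **Differential fingerprint** — subject-label permutation testing of
   the group difference in edgewise ICC, Benjamini–Hochberg FDR across
   all edges, and directional significant-edge masks with their ROI
   sets, summarized over the 28 network blocks.
5. **Topology & prediction** — the controls>patients mask filters each
   patient's FC; eight weighted graph measures (strength, eigenvector
   centrality, characteristic path length, mean first-passage time,
   modularity, participation coefficient, assortativity, rich-club
   coefficient) feed a nested leave-one-out cross-validated classifier
   of responder status (ΔUPDRS-III ≥ 15%), with label-permutation
   significance and mean-decrease-in-impurity feature importances.

Because cohorts of this kind are rarely shared, the package includes a
**synthetic cohort generator** (latent factor model with a planted
subject-unique component, group-specific edge-stability attenuation,
covariate effects and an outcome mechanism coupled to the planted
subnetwork) so the whole pipeline is testable against ground truth.

## Worked example

```r
library(brainfp)

cfg <- cohort_config(n_per_group = 12, n_regions = 40, n_timepoints = 300,
                     fingerprint_share = 0.5, group_share = 0.2, seed = 9)
cohort <- generate_cohort(cfg)

groups <- vapply(cohort$ts, function(t) t$group, character(1))
pairs  <- lapply(cohort$ts[groups == "control"], compute_split_fc)
test   <- edge_matrix(pairs, "test")
retest <- edge_matrix(pairs, "retest")
covs   <- cohort$covariates[cohort$covariates$group == "control", ]
test_r   <- residualize_edges(test, covs)
retest_r <- residualize_edges(retest, covs)

compute_identifiability_metrics(
  build_identifiability_matrix(test_r, retest_r))
#> <ident_metrics> mean I_self 0.476, mean I_others -0.043, I_diff 0.519, I_diff-norm 5.37, SR 100.0%

icc <- subsampled_icc(test_r, retest_r,
                      icc_subsample_config(n_iter = 100, fraction = 0.8, seed = 1))
icc
#> <icc_matrix> 40 regions, 12 subjects; mean edgewise ICC 0.454 (subsampled 100 x 80%)
network_icc_profile(icc, cohort$atlas)
#> <network_icc_profile>
#>    VN   SMN   DAN   VAN    LN   FPN   DMN
#> 0.153 0.598 0.582 0.569 0.537 0.566 0.633
#> whole brain 0.454; ranking: DMN > SMN > DAN > VAN > FPN > LN > VN
```

Reading the output: every control subject is correctly matched to
their own second scan half (SR = 100%), self-similarity (0.48) sits far
above the residualized cross-subject similarity (−0.04), and edgewise
reliability averages 0.45 ("fair" on the conventional bands). The
visual network's low within-network ICC (0.15) is the planted
control-group stability attenuation in the default configuration —
the generator's defaults plant patient attenuation in DMN-DMN/DAN-DMN
and control attenuation in VN-VN.

The whole chain (simulate → connectomes → identifiability → ICC →
differential masks → features → classification → statistics) can also
be run as one configured, artifact-writing pipeline:

```r
man <- run_pipeline(list(output_dir = "run1", seed = 7,
                         simulate = list(n_per_group = 10, n_regions = 50)))
```

`validate_config()` documents every setting and its default (1000
permutations and bootstrap iterations, 100 × 80% ICC subsampling,
FDR threshold 0.01, responder boundary 15%).

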