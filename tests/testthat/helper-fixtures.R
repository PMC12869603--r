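# Shared fixtures, generated once per test run and cached.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix_cache)) {
    assign(key, force(expr), envir = .fix_cache)
  }
  get(key, envir = .fix_cache)
}

# Strong-contrast study conditions used for the recovery, power and
# specificity properties: concentrated DMN/DAN planting, high fingerprint
# share and long scans so edgewise reliability effects are large relative
# to estimation noise at this problem size.
strong_contrast_config <- function(seed, outcome_coupling = 10,
                                   both_directions = FALSE) {
  blocks <- list(
    list(network_i = "DMN", network_j = "DMN",
         direction = "control_gt_patient", magnitude = 1.0),
    list(network_i = "DAN", network_j = "DMN",
         direction = "control_gt_patient", magnitude = 1.0))
  if (both_directions) {
    blocks <- c(blocks, list(
      list(network_i = "VN", network_j = "VN",
           direction = "patient_gt_control", magnitude = 1.0),
      list(network_i = "VN", network_j = "SMN",
           direction = "patient_gt_control", magnitude = 1.0)))
  }
  cohort_config(
    n_per_group = 24, n_regions = 30, n_timepoints = 800,
    fingerprint_share = 0.85, group_share = 0.05,
    outcome_coupling = outcome_coupling,
    network_sizes = c(VN = 4, SMN = 3, DAN = 7, VAN = 3, LN = 2,
                      FPN = 3, DMN = 8),
    stability_diff_blocks = blocks, seed = seed)
}

# Tiny null-condition config (no planted difference, no group component,
# so group labels are exchangeable) for type-I calibration.
null_toy_config <- function(seed) {
  cohort_config(
    n_per_group = 10, n_regions = 20, n_timepoints = 200,
    fingerprint_share = 0.5, group_share = 0,
    network_sizes = c(VN = 3, SMN = 3, DAN = 3, VAN = 3, LN = 2,
                      FPN = 3, DMN = 3),
    stability_diff_blocks = list(), seed = seed)
}

cohort_groups <- function(cohort) {
  vapply(cohort$ts, function(ts) ts$group, character(1))
}

# split-half edge matrices for one group, optionally residualized
group_halves <- function(cohort, group, residualize = FALSE) {
  grp <- cohort_groups(cohort)
  pairs <- lapply(cohort$ts[grp == group], compute_split_fc)
  te <- edge_matrix(pairs, "test")
  re <- edge_matrix(pairs, "retest")
  if (residualize) {
    covs <- cohort$covariates[cohort$covariates$group == group, ]
    te <- residualize_edges(te, covs)
    re <- residualize_edges(re, covs)
  }
  list(test = te, retest = re)
}

# full-series masked graph features for the patient group
patient_mask_features <- function(cohort, mask) {
  grp <- cohort_groups(cohort)
  pat <- which(grp == "patient")
  graphs <- lapply(cohort$ts[pat], function(ts) {
    suppressMessages(apply_edge_mask(stats::cor(ts$data), mask))
  })
  names(graphs) <- vapply(cohort$ts[pat], function(ts) ts$subject_id,
                          character(1))
  graph_feature_table(graphs)
}

# strong-contrast cohort plus the detected differential masks, cached
# because several property tests share it
recovery_run <- function(seed, both_directions = FALSE,
                         outcome_coupling = 10) {
  key <- sprintf("recovery_%d_%d_%g", seed, both_directions, outcome_coupling)
  cached(key, {
    cohort <- generate_cohort(strong_contrast_config(
      seed, outcome_coupling = outcome_coupling,
      both_directions = both_directions))
    perm <- permutation_test_icc_diff(
      group_halves(cohort, "control"), group_halves(cohort, "patient"),
      n_perm = 2000, seed = seed + 50)
    masks <- extract_edge_masks(perm$observed_diff, perm, alpha = 0.01)
    list(cohort = cohort, perm = perm, masks = masks)
  })
}

# single-row kNN spec: no inner tuning, keeps permutation re-runs cheap
fast_knn_spec <- function(seed = 1) {
  model_spec("k_nearest_neighbors",
             grid = data.frame(k = 5, weights = "uniform"),
             seed = seed)
}

expect_setequal_int <- function(a, b) expect_identical(sort(a), sort(b))
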