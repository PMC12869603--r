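edge_mats <- function(test_cols, retest_cols) {
  # columns are edges; builds matching subjects x edges matrices
  list(test = as.matrix(test_cols), retest = as.matrix(retest_cols))
}

test_that("edgewise ICC reproduces hand-worked one-way ANOVA cases", {
  # zero within-subject variance -> perfect reliability
  m <- edge_mats(cbind(c(1, 2, 3)), cbind(c(1, 2, 3)))
  expect_equal(compute_edgewise_icc(m$test, m$retest)$edge_values, 1.0)
  # zero between-subject variance, all disagreement within subjects
  m <- edge_mats(cbind(c(1, 2, 3)), cbind(c(3, 2, 1)))
  expect_equal(compute_edgewise_icc(m$test, m$retest)$edge_values, -1.0)
  # mixed case: MS_B = 57.1667, MS_W = 1/3
  m <- edge_mats(cbind(c(0, 0, 10)), cbind(c(0, 1, 9)))
  icc <- compute_edgewise_icc(m$test, m$retest)$edge_values
  expect_equal(icc, (57 + 1 / 6 - 1 / 3) / (57 + 1 / 6 + 1 / 3), tolerance = 1e-10)
  expect_equal(round(icc, 5), 0.98841)
})

test_that("vectorized ICC matches a brute-force aov oracle edge by edge", {
  set.seed(11)
  n <- 6
  e <- 10
  test <- matrix(rnorm(n * e), n, e)
  retest <- matrix(rnorm(n * e), n, e)
  icc <- compute_edgewise_icc(test, retest)$edge_values
  for (k in seq_len(e)) {
    d <- data.frame(y = c(test[, k], retest[, k]),
                    subj = factor(rep(seq_len(n), 2)))
    tab <- summary(stats::aov(y ~ subj, data = d))[[1]]
    msb <- tab["subj", "Mean Sq"]
    msw <- tab["Residuals", "Mean Sq"]
    expect_equal(icc[k], (msb - msw) / (msb + msw), tolerance = 1e-10)
  }
})

test_that("identical halves with any between-subject spread give ICC 1", {
  set.seed(12)
  test <- matrix(rnorm(8 * 15), 8, 15)
  icc <- compute_edgewise_icc(test, test)
  expect_true(all(icc$edge_values == 1))
  # fully constant edges are flagged as degenerate, not NaN-propagated
  test[, 1] <- 5
  icc2 <- compute_edgewise_icc(test, test)
  expect_true(is.na(icc2$edge_values[1]))
  expect_equal(icc2$n_degenerate, 1L)
})

test_that("subsampling at full fraction equals the plain estimate", {
  set.seed(13)
  test <- matrix(rnorm(10 * 21), 10, 21)
  retest <- test + matrix(rnorm(10 * 21, 0, 0.4), 10, 21)
  plain <- compute_edgewise_icc(test, retest)
  sub <- subsampled_icc(test, retest,
                        icc_subsample_config(n_iter = 7, fraction = 1, seed = 2))
  expect_equal(sub$edge_values, plain$edge_values)
  # determinism under a fixed seed
  cfg <- icc_subsample_config(n_iter = 25, fraction = 0.8, seed = 9)
  a <- subsampled_icc(test, retest, cfg)
  b <- subsampled_icc(test, retest, cfg)
  expect_identical(a$edge_values, b$edge_values)
  expect_error(subsampled_icc(test[1:3, ], retest[1:3, ],
                              icc_subsample_config(fraction = 0.5)),
               "< 3")
})

test_that("subsample means stabilize with iteration count", {
  set.seed(14)
  n <- 20
  sig <- matrix(rnorm(n * 30), n, 30)
  test <- sig + matrix(rnorm(n * 30, 0, 0.6), n, 30)
  retest <- sig + matrix(rnorm(n * 30, 0, 0.6), n, 30)
  few <- subsampled_icc(test, retest,
                        icc_subsample_config(n_iter = 100, fraction = 0.8, seed = 1))
  many <- subsampled_icc(test, retest,
                         icc_subsample_config(n_iter = 1000, fraction = 0.8, seed = 2))
  expect_lt(max(abs(few$edge_values - many$edge_values)), 0.02)
})

test_that("nodal strength sums incident reliability and flags hubs", {
  v <- matrix(0.5, 3, 3); diag(v) <- NA
  icc <- structure(list(values = v, edge_values = rep(0.5, 3),
                        n_subjects_used = 5, n_degenerate = 0,
                        subsample_config = NULL), class = "icc_matrix")
  ns <- icc_nodal_strength(icc)
  expect_equal(ns$strength, rep(1.0, 3))
  expect_false(any(ns$above_p75))
  # doubling one node's edges makes it the unique hub in a 5-node toy
  v5 <- matrix(0.3, 5, 5); diag(v5) <- NA
  v5[1, ] <- v5[, 1] <- 0.6; v5[1, 1] <- NA
  icc5 <- structure(list(values = v5, edge_values = v5[upper.tri(v5)],
                         n_subjects_used = 5, n_degenerate = 0,
                         subsample_config = NULL), class = "icc_matrix")
  ns5 <- icc_nodal_strength(icc5)
  expect_equal(which(ns5$above_p75), 1L)
  expect_equal(ns5$percentile[1], 100)
})

test_that("sentinel entries are excluded from nodal sums", {
  v <- matrix(0.4, 4, 4); diag(v) <- NA
  v[1, 2] <- v[2, 1] <- NA
  icc <- structure(list(values = v, edge_values = v[upper.tri(v)],
                        n_subjects_used = 4, n_degenerate = 1,
                        subsample_config = NULL), class = "icc_matrix")
  ns <- icc_nodal_strength(icc)
  expect_equal(ns$strength[1], 0.8)
  expect_equal(ns$strength[3], 1.2)
})

test_that("network profile averages within-network blocks and ranks them", {
  sizes <- c(VN = 3, SMN = 2, DAN = 2, VAN = 2, LN = 2, FPN = 2, DMN = 3)
  atlas <- atlas_table(sprintf("R%02d", 1:16),
                       network = rep(names(sizes), sizes))
  r <- 16
  v <- matrix(0.58, r, r); diag(v) <- NA
  icc <- structure(list(values = v, edge_values = v[upper.tri(v)],
                        n_subjects_used = 10, n_degenerate = 0,
                        subsample_config = NULL), class = "icc_matrix")
  prof <- network_icc_profile(icc, atlas)
  expect_equal(unname(prof$network_means), rep(0.58, 7))
  expect_equal(prof$whole_brain_mean, 0.58)
  # ties broken by the canonical network order
  expect_equal(prof$ranking, c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN"))
  # raising one network's block promotes it to rank one
  dmn <- which(atlas$network == "DMN")
  v2 <- v; v2[dmn, dmn] <- 0.78; diag(v2) <- NA
  icc2 <- icc; icc2$values <- v2
  prof2 <- network_icc_profile(icc2, atlas)
  expect_equal(prof2$ranking[1], "DMN")
  # whole-brain mean equals the mean over all upper-triangle edges
  expect_equal(prof2$whole_brain_mean,
               mean(v2[upper.tri(v2)], na.rm = TRUE), tolerance = 1e-12)
})

test_that("ranking concordance counts pairwise order agreements", {
  labs <- c("n1", "n2", "n3", "n4", "n5")
  res <- ranking_concordance(labs, labs, n_perm = 200, seed = 1)
  expect_equal(res$w, 1.0)
  expect_equal(ranking_concordance(labs, rev(labs), n_perm = 200, seed = 1)$w, 0.0)
  # (1..5) vs (2,1,4,3,5): 8 of 10 pairs concordant
  shuffled <- labs[c(2, 1, 4, 3, 5)]
  expect_equal(ranking_concordance(labs, shuffled, n_perm = 200, seed = 1)$w, 0.8)
  expect_error(ranking_concordance(labs, c(labs[-1], "zz"), n_perm = 10),
               "permutations of the same label set")
  # identical rankings are extreme under the shuffle null
  expect_lt(res$p_value, 0.05)
})

test_that("reliability bands follow the conventional cutpoints", {
  expect_equal(as.character(icc_band(c(0.39, 0.4, 0.59, 0.6, 0.74, 0.75, -0.2))),
               c("poor", "fair", "fair", "good", "good", "excellent", "poor"))
})

test_that("planted attenuation lowers block reliability monotonically", {
  mean_block_icc <- vapply(c(0, 0.5, 1), function(mag) {
    cfg <- cohort_config(
      n_per_group = 12, n_regions = 20, n_timepoints = 300,
      fingerprint_share = 0.7, group_share = 0.1,
      network_sizes = c(VN = 3, SMN = 3, DAN = 3, VAN = 3, LN = 2,
                        FPN = 3, DMN = 3),
      stability_diff_blocks = list(
        list(network_i = "DMN", network_j = "DMN",
             direction = "control_gt_patient", magnitude = mag)),
      seed = 21)
    cohort <- generate_cohort(cfg)
    halves <- group_halves(cohort, "patient")
    icc <- compute_edgewise_icc(halves$test, halves$retest)
    truth <- cohort$ground_truth$true_differential_edges$control_gt_patient
    mean(icc$edge_values[truth])
  }, numeric(1))
  expect_true(all(diff(mean_block_icc) < 0))
})
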