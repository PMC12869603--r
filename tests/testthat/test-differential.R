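fake_icc <- function(edge_values) {
  structure(list(values = devectorize_fc(edge_values, diag_value = NA_real_),
                 edge_values = edge_values, n_subjects_used = 10,
                 n_degenerate = 0, subsample_config = NULL),
            class = "icc_matrix")
}

test_that("differential map is an antisymmetric elementwise difference", {
  a <- fake_icc(c(0.9, 0.9, 0.9))
  b <- fake_icc(c(0.4, 0.4, 0.4))
  d_ab <- compute_icc_diff(a, b)
  expect_equal(d_ab$edge_values, rep(0.5, 3))
  d_ba <- compute_icc_diff(b, a)
  expect_equal(d_ba$edge_values, -d_ab$edge_values)
  expect_equal(compute_icc_diff(a, a)$edge_values, rep(0, 3))
})

test_that("BH adjustment matches an independently coded step-up reference", {
  bh_reference <- function(p) {
    m <- length(p)
    o <- order(p)
    scaled <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(scaled)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(31)
  for (rep in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_reference(p), tolerance = 1e-12)
  }
  # worked example from a three-metric family
  expect_equal(bh_adjust(c(0.004, 0.009, 0.5)), c(0.012, 0.0135, 0.5),
               tolerance = 1e-12)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("permutation maps are deterministic and bounded below by the floor", {
  set.seed(32)
  n <- 5; e <- 6
  pa <- list(test = matrix(rnorm(n * e), n, e),
             retest = matrix(rnorm(n * e), n, e))
  pb <- list(test = matrix(rnorm(n * e), n, e),
             retest = matrix(rnorm(n * e), n, e))
  r1 <- suppressWarnings(permutation_test_icc_diff(pa, pb, n_perm = 60, seed = 5))
  r2 <- suppressWarnings(permutation_test_icc_diff(pa, pb, n_perm = 60, seed = 5))
  expect_identical(r1$p_raw, r2$p_raw)
  expect_true(all(r1$p_raw >= 1 / 61 & r1$p_raw <= 1))
  expect_true(all(r1$p_adj >= r1$p_raw - 1e-15))
  expect_warning(permutation_test_icc_diff(pa, pb, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("directional masks partition significant edges by sign", {
  diff <- structure(list(
    values = devectorize_fc(c(0.5, -0.4, 0.6, 0.1, 0, 0), diag_value = NA_real_),
    edge_values = c(0.5, -0.4, 0.6, 0.1, 0, 0)), class = "icc_diff_matrix")
  perm <- structure(list(p_adj = c(0.001, 0.002, 0.003, 0.5, 0.9, 0.9),
                         p_raw = rep(0.001, 6)),
                    class = "edge_permutation_result")
  masks <- extract_edge_masks(diff, perm, alpha = 0.01)
  # positive-significant edges (1,2) and (1,4) share region 1 -> 3 ROIs
  expect_equal(masks$a_gt_b$n_edges, 2L)
  expect_equal(masks$a_gt_b$roi_set, c(1L, 2L, 4L))
  expect_equal(masks$a_gt_b$n_rois, 3L)
  expect_equal(masks$b_gt_a$n_edges, 1L)
  expect_equal(masks$b_gt_a$roi_set, c(1L, 3L))
  # exhaustive and disjoint over significant edges
  sig <- perm$p_adj < 0.01 & diff$edge_values != 0
  expect_equal(masks$a_gt_b$edges | masks$b_gt_a$edges, sig)
  expect_false(any(masks$a_gt_b$edges & masks$b_gt_a$edges))
  expect_error(extract_edge_masks(diff, perm, alpha = 1.2), "alpha")
})

test_that("swapping the group arguments swaps the two masks exactly", {
  run <- recovery_run(1)
  perm_sw <- permutation_test_icc_diff(
    group_halves(run$cohort, "patient"), group_halves(run$cohort, "control"),
    n_perm = 300, seed = 77)
  perm_fw <- permutation_test_icc_diff(
    group_halves(run$cohort, "control"), group_halves(run$cohort, "patient"),
    n_perm = 300, seed = 77)
  m_fw <- extract_edge_masks(perm_fw$observed_diff, perm_fw, alpha = 0.01)
  m_sw <- extract_edge_masks(perm_sw$observed_diff, perm_sw, alpha = 0.01)
  expect_equal(perm_sw$observed_diff$edge_values,
               -perm_fw$observed_diff$edge_values)
  expect_identical(m_fw$a_gt_b$edges, m_sw$b_gt_a$edges)
  expect_identical(m_fw$b_gt_a$edges, m_sw$a_gt_b$edges)
})

test_that("block summary normalizes significant strength across 28 blocks", {
  sizes <- c(VN = 2, SMN = 2, DAN = 2, VAN = 2, LN = 2, FPN = 2, DMN = 2)
  atlas <- atlas_table(sprintf("R%02d", 1:14), network = rep(names(sizes), sizes))
  e <- nrow(edge_index(14))
  ev <- rep(0, e)
  idx <- edge_index(14)
  # all significant weight inside the VN-VN block (edge 1-2)
  vn_edge <- which(idx$i == 1 & idx$j == 2)
  ev[vn_edge] <- 0.6
  diff <- structure(list(values = devectorize_fc(ev, diag_value = NA_real_),
                         edge_values = ev), class = "icc_diff_matrix")
  masks <- list(
    a_gt_b = structure(list(direction = "a_gt_b",
                            edges = seq_len(e) == vn_edge,
                            roi_set = c(1L, 2L), n_edges = 1L, n_rois = 2L,
                            alpha = 0.01), class = "edge_mask"),
    b_gt_a = structure(list(direction = "b_gt_a",
                            edges = rep(FALSE, e),
                            roi_set = integer(0), n_edges = 0L, n_rois = 0L,
                            alpha = 0.01), class = "edge_mask"))
  bs <- network_block_summary(diff, masks, atlas)
  expect_equal(bs$block_strengths$a_gt_b["VN", "VN"], 1.0)
  expect_equal(sum(bs$block_strengths$a_gt_b) + sum(bs$block_strengths$b_gt_a), 1.0)
  expect_equal(bs$n_blocks_hit, 1L)
  expect_equal(bs$coverage_fraction, 1.0)
  # two equal-strength blocks split the normalized total evenly
  dmn_edge <- which(idx$i == 13 & idx$j == 14)
  ev2 <- ev; ev2[dmn_edge] <- -0.6
  diff2 <- structure(list(values = devectorize_fc(ev2, diag_value = NA_real_),
                          edge_values = ev2), class = "icc_diff_matrix")
  masks2 <- masks
  masks2$b_gt_a$edges[dmn_edge] <- TRUE
  masks2$b_gt_a$n_edges <- 1L
  bs2 <- network_block_summary(diff2, masks2, atlas)
  expect_equal(bs2$block_strengths$a_gt_b["VN", "VN"], 0.5)
  expect_equal(bs2$block_strengths$b_gt_a["DMN", "DMN"], 0.5)
  expect_equal(bs2$n_blocks_hit, 2L)
})

test_that("attenuated network blocks carry most of the significant strength", {
  run <- recovery_run(2)
  bs <- network_block_summary(run$perm$observed_diff, run$masks,
                              run$cohort$atlas)
  s <- bs$block_strengths$a_gt_b
  # remixing DMN and DAN rows attenuates every edge incident to those
  # regions, so essentially all significant strength must sit in blocks
  # involving DMN or DAN, and none elsewhere
  touches <- outer(rownames(s) %in% c("DMN", "DAN"),
                   colnames(s) %in% c("DMN", "DAN"), `|`)
  expect_gt(sum(s[touches]), 0.95)
  expect_lt(sum(s[!touches]), 0.05)
  # the single strongest block involves an attenuated network
  top <- which(s == max(s), arr.ind = TRUE)[1, ]
  expect_true(any(rownames(s)[top] %in% c("DMN", "DAN")))
  expect_gt(bs$coverage_fraction, 0)
  expect_lte(bs$coverage_fraction, 1)
})
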