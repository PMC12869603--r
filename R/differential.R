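#' Differential ICC map between groups
#'
#' Elementwise difference of two edgewise reliability maps (group A minus
#' group B); positive entries mark edges more reliable in group A.
#'
#' @param icc_a,icc_b `icc_matrix` objects on the same atlas and edge
#'   ordering.
#' @return object of class `icc_diff_matrix`: `values` (R x R), and
#'   `edge_values` (length E).
#' @export
compute_icc_diff <- function(icc_a, icc_b) {
  stopifnot(inherits(icc_a, "icc_matrix"), inherits(icc_b, "icc_matrix"))
  if (length(icc_a$edge_values) != length(icc_b$edge_values)) {
    stop_brainfp("ICC matrices have mismatched shapes")
  }
  edge_values <- icc_a$edge_values - icc_b$edge_values
  values <- if (!is.null(icc_a$values)) {
    devectorize_fc(edge_values, diag_value = NA_real_)
  } else {
    NULL
  }
  structure(list(values = values, edge_values = edge_values),
            class = "icc_diff_matrix")
}

#' Permutation test for group differences in edgewise ICC
#'
#' Tests, at every edge, whether the observed reliability difference
#' between the two groups exceeds what label exchange would produce.
#' Whole subjects are reassigned: each permutation shuffles group labels
#' over the pooled cohort while keeping every subject's test/retest pair
#' intact (preserving the temporal structure), recomputes edgewise ICC
#' per permuted group, and stores the difference. The per-edge two-sided
#' empirical p-value is the (plus-one corrected) proportion of
#' permutations with absolute null difference at least as large as the
#' observed one; Benjamini-Hochberg adjustment is then applied jointly
#' across all E edges.
#'
#' @param pairs_a,pairs_b lists with elements `test` and `retest`
#'   (subjects x edges matrices) for the two groups.
#' @param n_perm permutation iterations (default 1000).
#' @param seed RNG seed.
#' @param subsample optional [icc_subsample_config()]; when supplied, both
#'   the observed maps and every permutation use subsample-averaged ICC
#'   (the same configuration as the observed statistic). `NULL` (full
#'   sample, fast mode) by default.
#' @return object of class `edge_permutation_result`: `observed_diff`
#'   (an `icc_diff_matrix`), `p_raw`, `p_adj` (length-E vectors),
#'   `n_perm`, `seed`, `subsample`.
#' @export
permutation_test_icc_diff <- function(pairs_a, pairs_b, n_perm = 1000,
                                      seed = 1, subsample = NULL) {
  for (p in list(pairs_a, pairs_b)) {
    stopifnot(is.matrix(p$test), is.matrix(p$retest))
  }
  if (n_perm < 100) warning("n_perm < 100: permutation p-values will be coarse")
  n_a <- nrow(pairs_a$test)
  n_b <- nrow(pairs_b$test)
  if (n_a < 3 || n_b < 3) stop_brainfp("need at least 3 subjects per group")
  icc_of <- function(test, retest) {
    if (is.null(subsample)) {
      icc_from_halves(test, retest)
    } else {
      subsampled_icc(test, retest, subsample)$edge_values
    }
  }
  obs_a <- icc_of(pairs_a$test, pairs_a$retest)
  obs_b <- icc_of(pairs_b$test, pairs_b$retest)
  observed <- obs_a - obs_b
  pool_test <- rbind(pairs_a$test, pairs_b$test)
  pool_retest <- rbind(pairs_a$retest, pairs_b$retest)
  n_tot <- n_a + n_b
  # canonical subject order so the null draws (hence p-values) are
  # invariant under swapping the two group arguments
  ids <- rownames(pool_test)
  if (!is.null(ids) && !anyDuplicated(ids)) {
    ord <- order(ids)
    pool_test <- pool_test[ord, , drop = FALSE]
    pool_retest <- pool_retest[ord, , drop = FALSE]
  }
  exceed <- with_seed(seed, {
    count <- integer(length(observed))
    for (it in seq_len(n_perm)) {
      idx_a <- sample.int(n_tot, n_a, replace = FALSE)
      null_diff <-
        icc_of(pool_test[idx_a, , drop = FALSE],
               pool_retest[idx_a, , drop = FALSE]) -
        icc_of(pool_test[-idx_a, , drop = FALSE],
               pool_retest[-idx_a, , drop = FALSE])
      count <- count + (abs(null_diff) >= abs(observed))
    }
    count
  })
  p_raw <- (1 + exceed) / (n_perm + 1)
  structure(
    list(observed_diff = structure(
           list(values = devectorize_fc(observed, diag_value = NA_real_),
                edge_values = observed),
           class = "icc_diff_matrix"),
         p_raw = p_raw, p_adj = bh_adjust(p_raw),
         n_perm = n_perm, seed = seed, subsample = subsample),
    class = "edge_permutation_result"
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with the m p-values sorted
#' ascending, `p_adj(i) = min_{j >= i}(p(j) * m / j)` capped at 1,
#' reported in the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_brainfp("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Directional significant-edge masks
#'
#' Splits the edges surviving the adjusted significance threshold by the
#' sign of the observed reliability difference: edges more reliable in
#' group A (`a_gt_b`) and edges more reliable in group B (`b_gt_a`).
#' Each mask also carries the set of unique regions its edges touch,
#' which is what downstream feature extraction masks subject connectomes
#' with.
#'
#' @param diff an `icc_diff_matrix` (group A minus group B).
#' @param perm the matching `edge_permutation_result`.
#' @param alpha significance level on adjusted p-values (default 0.01).
#' @return list with elements `a_gt_b` and `b_gt_a`, each an `edge_mask`:
#'   `direction`, `edges` (logical length E), `roi_set` (integer region
#'   indices), `n_edges`, `n_rois`, `alpha`.
#' @export
extract_edge_masks <- function(diff, perm, alpha = 0.01) {
  stopifnot(inherits(diff, "icc_diff_matrix"),
            inherits(perm, "edge_permutation_result"))
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_brainfp("alpha must be in (0, 1)")
  }
  e <- length(diff$edge_values)
  if (length(perm$p_adj) != e) stop_brainfp("edge count mismatch")
  sig <- perm$p_adj < alpha & !is.na(diff$edge_values)
  idx <- edge_index(nrow(diff$values))
  make_mask <- function(direction, keep) {
    rois <- sort(unique(c(idx$i[keep], idx$j[keep])))
    structure(
      list(direction = direction, edges = keep, roi_set = rois,
           n_edges = sum(keep), n_rois = length(rois), alpha = alpha),
      class = "edge_mask"
    )
  }
  list(
    a_gt_b = make_mask("a_gt_b", sig & diff$edge_values > 0),
    b_gt_a = make_mask("b_gt_a", sig & diff$edge_values < 0)
  )
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> %s: %d edges over %d unique ROIs (alpha = %g)\n",
              x$direction, x$n_edges, x$n_rois, x$alpha))
  invisible(x)
}

#' Network-block summary of significant reliability differences
#'
#' Aggregates the significant edges into the 28 network blocks (7 within-
#' plus 21 between-network combinations), summing the absolute observed
#' ICC difference per block and normalizing by the combined total over
#' both directions, so block strengths are shares of the total
#' significant differential reliability.
#'
#' @param diff an `icc_diff_matrix`.
#' @param masks the mask pair from [extract_edge_masks()].
#' @param atlas an [atlas_table()] in region order.
#' @return object of class `network_block_summary`: `block_strengths`
#'   (list of two 7 x 7 matrices, upper-triangle-plus-diagonal blocks,
#'   one per direction), `n_blocks_hit`, `coverage_fraction`.
#' @export
network_block_summary <- function(diff, masks, atlas) {
  stopifnot(inherits(diff, "icc_diff_matrix"))
  r <- nrow(diff$values)
  if (nrow(atlas) != r) stop_brainfp("atlas does not match matrix size")
  idx <- edge_index(r)
  net <- factor(atlas$network, levels = NETWORK_LABELS)
  net_i <- as.integer(net[idx$i])
  net_j <- as.integer(net[idx$j])
  block_row <- pmin(net_i, net_j)
  block_col <- pmax(net_i, net_j)
  block_id <- (block_row - 1L) * 7L + block_col
  total_abs <- sum(abs(diff$edge_values), na.rm = TRUE)
  per_direction <- lapply(masks, function(m) {
    s <- matrix(0, 7, 7, dimnames = list(NETWORK_LABELS, NETWORK_LABELS))
    keep <- m$edges
    if (any(keep)) {
      sums <- tapply(abs(diff$edge_values[keep]), block_id[keep], sum)
      for (k in seq_along(sums)) {
        b <- as.integer(names(sums)[k])
        s[((b - 1L) %/% 7L) + 1L, ((b - 1L) %% 7L) + 1L] <- sums[k]
      }
    }
    s
  })
  combined_total <- sum(vapply(per_direction, sum, numeric(1)))
  if (combined_total > 0) {
    per_direction <- lapply(per_direction, function(s) s / combined_total)
  }
  hit <- Reduce(`+`, lapply(per_direction, function(s) s > 0))
  structure(
    list(block_strengths = per_direction,
         n_blocks_hit = sum(hit[upper.tri(hit, diag = TRUE)] > 0),
         coverage_fraction = if (total_abs > 0) combined_total / total_abs
                             else NA_real_),
    class = "network_block_summary"
  )
}
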