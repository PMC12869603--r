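#' Edgewise test-retest reliability via ICC(1,1)
#'
#' For every edge, fits the one-way random-effects ANOVA across subjects
#' with k = 2 repeated measurements (test and retest) and computes
#' `ICC(1,1) = (MS_B - MS_W) / (MS_B + (k - 1) MS_W)`, where `MS_B` is the
#' between-subject mean square (df N - 1) and `MS_W` the within-subject
#' mean square (df N(k - 1)). Negative values are retained — they signal
#' within-subject fluctuation exceeding between-subject spread. Edges
#' whose 2N values are all identical have an undefined ICC and are stored
#' as `NA` (counted in `n_degenerate`).
#'
#' @param test,retest subjects x edges matrices with matching dimensions.
#' @return object of class `icc_matrix`: `values` (R x R symmetric matrix,
#'   `NA` diagonal), `edge_values` (length-E vector), `n_subjects_used`,
#'   `n_degenerate`, `subsample_config` (`NULL` here).
#' @export
compute_edgewise_icc <- function(test, retest) {
  stopifnot(is.matrix(test), is.matrix(retest))
  if (!identical(dim(test), dim(retest))) {
    stop_brainfp("test and retest matrices must share dimensions")
  }
  n <- nrow(test)
  if (n < 3) stop_brainfp("need at least 3 subjects, got %d", n)
  icc <- icc_from_halves(test, retest)
  new_icc_matrix(icc, n_subjects_used = n, subsample_config = NULL)
}

# vectorized one-way ANOVA ICC over edge columns; returns length-E vector
icc_from_halves <- function(test, retest) {
  n <- nrow(test)
  subj_mean <- (test + retest) / 2
  grand <- colMeans(subj_mean)
  msb <- 2 * colSums(sweep(subj_mean, 2, grand, "-")^2) / (n - 1)
  msw <- colSums((test - retest)^2) / (2 * n)
  denom <- msb + msw
  icc <- ifelse(denom == 0, NA_real_, (msb - msw) / denom)
  unname(icc)
}

new_icc_matrix <- function(edge_values, n_subjects_used, subsample_config) {
  # the square map exists only when the edge count is triangular
  # (R(R-1)/2 for some R); arbitrary edge subsets keep the vector form
  e <- length(edge_values)
  r <- (1 + sqrt(1 + 8 * e)) / 2
  values <- if (abs(r - round(r)) < 1e-9) {
    devectorize_fc(edge_values, diag_value = NA_real_)
  } else {
    NULL
  }
  structure(
    list(values = values, edge_values = edge_values,
         n_subjects_used = n_subjects_used,
         n_degenerate = sum(is.na(edge_values)),
         subsample_config = subsample_config),
    class = "icc_matrix"
  )
}

#' @export
print.icc_matrix <- function(x, ...) {
  cat(sprintf("<icc_matrix> %s regions, %d subjects; mean edgewise ICC %.3f%s\n",
              if (is.null(x$values)) "?" else nrow(x$values), x$n_subjects_used,
              mean(x$edge_values, na.rm = TRUE),
              if (is.null(x$subsample_config)) "" else
                sprintf(" (subsampled %d x %.0f%%)",
                        x$subsample_config$n_iter,
                        100 * x$subsample_config$fraction)))
  invisible(x)
}

#' Subsampling configuration for ICC estimation
#'
#' @param n_iter number of random subsamples (default 100).
#' @param fraction fraction of subjects per draw, sampled without
#'   replacement (default 0.8).
#' @param seed RNG seed.
#' @return object of class `icc_subsample_config`.
#' @export
icc_subsample_config <- function(n_iter = 100, fraction = 0.8, seed = 1) {
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    stop_brainfp("fraction must be in (0, 1]")
  }
  if (n_iter < 1) stop_brainfp("n_iter must be positive")
  structure(list(n_iter = as.integer(n_iter), fraction = fraction,
                 seed = as.integer(seed)),
            class = "icc_subsample_config")
}

#' Subsample-averaged edgewise ICC
#'
#' Stabilizes edgewise ICC estimates by repeated random subsampling:
#' at each of `cfg$n_iter` iterations a fraction of subjects (default 80%)
#' is drawn without replacement, edgewise ICC is computed on the
#' subsample, and the resulting maps are averaged.
#'
#' @param test,retest subjects x edges matrices.
#' @param cfg an [icc_subsample_config()].
#' @return an `icc_matrix` whose values are subsample means.
#' @export
subsampled_icc <- function(test, retest, cfg = icc_subsample_config()) {
  stopifnot(inherits(cfg, "icc_subsample_config"))
  n <- nrow(test)
  n_sub <- floor(cfg$fraction * n)
  if (n_sub < 3) {
    stop_brainfp("subsample size %d < 3 (fraction %.2f of %d subjects)",
                 n_sub, cfg$fraction, n)
  }
  if (n_sub == n) {
    out <- compute_edgewise_icc(test, retest)
    out$subsample_config <- cfg
    return(out)
  }
  acc <- with_seed(cfg$seed, {
    total <- 0
    for (it in seq_len(cfg$n_iter)) {
      idx <- sample.int(n, n_sub, replace = FALSE)
      total <- total + icc_from_halves(test[idx, , drop = FALSE],
                                       retest[idx, , drop = FALSE])
    }
    total / cfg$n_iter
  })
  new_icc_matrix(acc, n_subjects_used = n, subsample_config = cfg)
}

#' Nodal ICC strength and percentile ranks
#'
#' Node strength is the sum of ICC values over all edges attached to the
#' node (undefined entries excluded). Percentile ranks are reported in
#' \[0, 100\] and nodes above the 75th percentile are flagged, the
#' conventional cut for "high reliability hubs".
#'
#' @param icc an `icc_matrix`.
#' @return data.frame with `region`, `strength`, `percentile`,
#'   `above_p75`.
#' @export
icc_nodal_strength <- function(icc) {
  stopifnot(inherits(icc, "icc_matrix"))
  v <- icc$values
  strength <- rowSums(v, na.rm = TRUE)
  n <- length(strength)
  percentile <- if (n > 1) 100 * (rank(strength, ties.method = "average") - 1) / (n - 1) else 50
  data.frame(
    region = rownames(v) %||% sprintf("R%03d", seq_len(n)),
    strength = strength,
    percentile = percentile,
    above_p75 = strength > stats::quantile(strength, 0.75),
    row.names = NULL
  )
}

#' Atlas lookup table constructor
#'
#' @param region_id,region_name,network character vectors of equal length;
#'   `network` must use exactly the 7 canonical labels
#'   (VN, SMN, DAN, VAN, LN, FPN, DMN).
#' @return data.frame of class `atlas_table`.
#' @export
atlas_table <- function(region_id, region_name = region_id, network) {
  network <- as.character(network)
  if (!all(network %in% NETWORK_LABELS)) {
    stop_brainfp("unknown network label(s): %s",
                 paste(setdiff(unique(network), NETWORK_LABELS), collapse = ", "))
  }
  if (length(unique(network)) != 7) {
    stop_brainfp("atlas must cover exactly 7 networks, found %d",
                 length(unique(network)))
  }
  out <- data.frame(region_id = as.character(region_id),
                    region_name = as.character(region_name),
                    network = network)
  class(out) <- c("atlas_table", "data.frame")
  out
}

#' Network-level ICC profile
#'
#' Averages the upper-triangle edges inside each network's submatrix
#' (after ordering regions by network assignment) to obtain 7
#' within-network means, plus the whole-brain mean over all
#' upper-triangle edges, and ranks the networks by mean ICC (ties broken
#' by the fixed canonical network order).
#'
#' @param icc an `icc_matrix`.
#' @param atlas an [atlas_table()] covering all regions, in region order.
#' @return object of class `network_icc_profile`: `network_means` (named,
#'   canonical order), `whole_brain_mean`, `ranking` (labels, best
#'   first).
#' @export
network_icc_profile <- function(icc, atlas) {
  stopifnot(inherits(icc, "icc_matrix"))
  v <- icc$values
  if (nrow(atlas) != nrow(v)) {
    stop_brainfp("atlas covers %d regions but ICC matrix has %d",
                 nrow(atlas), nrow(v))
  }
  sizes <- table(factor(atlas$network, levels = NETWORK_LABELS))
  if (any(sizes < 2)) {
    stop_brainfp("network(s) with < 2 regions: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  ut <- upper.tri(v)
  means <- vapply(NETWORK_LABELS, function(net) {
    in_net <- atlas$network == net
    block <- v[in_net, in_net, drop = FALSE]
    mean(block[upper.tri(block)], na.rm = TRUE)
  }, numeric(1))
  whole <- mean(v[ut], na.rm = TRUE)
  ord <- order(-means, match(names(means), NETWORK_LABELS))
  structure(
    list(network_means = means, whole_brain_mean = whole,
         ranking = names(means)[ord]),
    class = "network_icc_profile"
  )
}

#' @export
print.network_icc_profile <- function(x, ...) {
  cat("<network_icc_profile>\n")
  print(round(x$network_means, 3))
  cat(sprintf("whole brain %.3f; ranking: %s\n", x$whole_brain_mean,
              paste(x$ranking, collapse = " > ")))
  invisible(x)
}

# proportion of label pairs with the same relative order in two rankings
pairwise_concordance <- function(rank_a, rank_b) {
  labs <- rank_a
  pos_a <- match(labs, rank_a)
  pos_b <- match(labs, rank_b)
  pairs <- utils::combn(seq_along(labs), 2)
  same <- sign(pos_a[pairs[1, ]] - pos_a[pairs[2, ]]) ==
    sign(pos_b[pairs[1, ]] - pos_b[pairs[2, ]])
  mean(same)
}

#' Ranking concordance with permutation test
#'
#' Quantifies the agreement of two network rankings as the proportion of
#' label pairs with the same relative order, and assesses it against a
#' null distribution obtained by randomly shuffling the second ranking
#' (one-sided: high concordance means similar rankings).
#'
#' @param rank_a,rank_b character vectors, permutations of the same label
#'   set (best first).
#' @param n_perm permutation iterations (default 1000).
#' @param seed RNG seed.
#' @return object of class `concordance_result`: `w`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
ranking_concordance <- function(rank_a, rank_b, n_perm = 1000, seed = 1) {
  if (!setequal(rank_a, rank_b) || length(rank_a) != length(rank_b) ||
      anyDuplicated(rank_a) || anyDuplicated(rank_b)) {
    stop_brainfp("rankings must be permutations of the same label set")
  }
  w_obs <- pairwise_concordance(rank_a, rank_b)
  w_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pairwise_concordance(rank_a, sample(rank_b))
    }, numeric(1))
  })
  p <- (1 + sum(w_null >= w_obs)) / (n_perm + 1)
  structure(list(w = w_obs, p_value = p, n_perm = n_perm, seed = seed),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> W = %.3f, p = %.3f (%d permutations)\n",
              x$w, x$p_value, x$n_perm))
  invisible(x)
}

#' Interpretation band for ICC values
#'
#' Maps reliability coefficients onto the conventional qualitative bands:
#' poor below 0.4, fair 0.4-0.59, good 0.6-0.74, excellent at or above
#' 0.75.
#'
#' @param icc numeric vector of ICC values.
#' @return factor with levels poor, fair, good, excellent.
#' @export
icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.4, 0.6, 0.75, Inf),
      labels = c("poor", "fair", "good", "excellent"), right = FALSE)
}
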