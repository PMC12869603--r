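#' Weighted undirected graph container
#'
#' @param weights symmetric non-negative matrix with zero diagonal.
#' @param nodes node labels (defaults to rownames or indices).
#' @param provenance free-form tag describing how the graph was built
#'   (mask name or density).
#' @return object of class `weighted_graph`.
#' @export
weighted_graph <- function(weights, nodes = NULL, provenance = "manual") {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop_brainfp("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop_brainfp("weights must be symmetric")
  }
  if (any(weights < 0)) stop_brainfp("weights must be non-negative")
  diag(weights) <- 0
  if (is.null(nodes)) {
    nodes <- rownames(weights) %||% as.character(seq_len(nrow(weights)))
  }
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights, provenance = provenance),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> %d nodes, %d edges (%s)\n",
              nrow(x$weights), sum(x$weights[upper.tri(x$weights)] > 0),
              x$provenance))
  invisible(x)
}

#' Mask a connectome down to the discriminative subnetwork
#'
#' Applies a significant-edge mask to a subject's FC matrix, retaining
#' (by default) exactly the mask's edges with absolute FC as weights;
#' the alternative `roi` mode keeps every edge among the regions the
#' mask touches. Nodes left without any retained connection are dropped
#' (with a message).
#'
#' @param fc R x R (residualized) FC matrix on the full atlas.
#' @param mask an `edge_mask` from [extract_edge_masks()].
#' @param weight_mode `"absolute"` (default) uses |FC|;
#'   `"positive_only"` zeroes negative correlations.
#' @param mode `"edge"` retains the mask's edges only (default);
#'   `"roi"` retains the induced subgraph on the mask's ROI set.
#' @return a [weighted_graph()].
#' @export
apply_edge_mask <- function(fc, mask,
                            weight_mode = c("absolute", "positive_only"),
                            mode = c("edge", "roi")) {
  weight_mode <- match.arg(weight_mode)
  mode <- match.arg(mode)
  stopifnot(inherits(mask, "edge_mask"))
  fc <- as.matrix(fc)
  r <- nrow(fc)
  idx <- edge_index(r)
  if (length(mask$edges) != nrow(idx)) {
    stop_brainfp("mask and FC matrix use different region counts")
  }
  if (mask$n_edges == 0) stop_brainfp("empty discriminative subnetwork")
  w_full <- if (weight_mode == "absolute") abs(fc) else pmax(fc, 0)
  keep <- matrix(FALSE, r, r)
  if (mode == "edge") {
    ii <- idx$i[mask$edges]; jj <- idx$j[mask$edges]
    keep[cbind(ii, jj)] <- TRUE
    keep[cbind(jj, ii)] <- TRUE
  } else {
    keep[mask$roi_set, mask$roi_set] <- TRUE
  }
  w <- ifelse(keep, w_full, 0)
  diag(w) <- 0
  nodes <- mask$roi_set
  w <- w[nodes, nodes, drop = FALSE]
  labels <- (rownames(fc) %||% as.character(seq_len(r)))[nodes]
  strengths <- rowSums(w)
  if (any(strengths == 0)) {
    message(sprintf("dropping %d isolated node(s) after masking",
                    sum(strengths == 0)))
    w <- w[strengths > 0, strengths > 0, drop = FALSE]
    labels <- labels[strengths > 0]
  }
  weighted_graph(w, nodes = labels,
                 provenance = sprintf("mask:%s", mask$direction))
}

#' Proportional thresholding of a connectome
#'
#' Retains the top `ceiling(density * E)` edges by absolute FC and zeroes
#' the rest, producing a non-negative weighted graph at a fixed density.
#' Ties at the cut are broken by edge-index order (and logged).
#'
#' @param fc R x R FC matrix.
#' @param density fraction of edges to keep, in (0, 1].
#' @return a [weighted_graph()] on all R nodes.
#' @export
proportional_threshold <- function(fc, density) {
  if (!is_scalar_number(density) || density <= 0 || density > 1) {
    stop_brainfp("density must be in (0, 1]")
  }
  fc <- as.matrix(fc)
  r <- nrow(fc)
  aw <- abs(fc)
  vals <- aw[upper_tri_rowmajor(r)]
  n_keep <- ceiling(density * length(vals))
  ord <- order(-vals, seq_along(vals))  # ties -> lower edge index wins
  kept <- ord[seq_len(n_keep)]
  cutoff <- vals[kept[n_keep]]
  if (sum(vals == cutoff) > 1 && n_keep < length(vals)) {
    message(sprintf("proportional_threshold: tie at cutoff %.6g broken by edge order",
                    cutoff))
  }
  out_vals <- numeric(length(vals))
  out_vals[kept] <- vals[kept]
  w <- devectorize_fc(out_vals, diag_value = 0)
  dimnames(w) <- dimnames(fc)
  weighted_graph(w, provenance = sprintf("density:%.2f", density))
}

#' Density grid for proportional thresholding
#'
#' @param densities grid of densities, default 0.05 to 0.95 in steps of
#'   0.05.
#' @return validated numeric vector.
#' @export
threshold_config <- function(densities = seq(0.05, 0.95, by = 0.05)) {
  if (any(densities <= 0 | densities > 1)) {
    stop_brainfp("all densities must be in (0, 1]")
  }
  densities
}

# principal eigenvector of a non-negative symmetric matrix via power
# iteration (deterministic start from the strength vector)
principal_eigenvector <- function(w, tol = 1e-12, max_iter = 10000) {
  v <- rowSums(w)
  if (all(v == 0)) stop_brainfp("graph has no edges")
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(max_iter)) {
    nv <- as.vector(w %*% v)
    nrm <- sqrt(sum(nv^2))
    if (nrm == 0) break
    nv <- nv / nrm
    if (max(abs(nv - v)) < tol) {
      v <- nv
      break
    }
    v <- nv
  }
  abs(v)
}

# mean first-passage time matrix of the random walk on a connected
# weighted graph, via the fundamental matrix Z = (I - P + 1 pi')^{-1}:
# mfpt[i, j] = (Z[j, j] - Z[i, j]) / pi[j]
mfpt_matrix <- function(w) {
  k <- rowSums(w)
  p <- w / k
  pi_s <- k / sum(k)
  n <- nrow(w)
  z <- solve(diag(n) - p + matrix(pi_s, n, n, byrow = TRUE))
  m <- (matrix(diag(z), n, n, byrow = TRUE) - z) /
    matrix(pi_s, n, n, byrow = TRUE)
  diag(m) <- 0
  m
}

# participation coefficient of each node against a community partition
participation_coefficient <- function(w, membership) {
  k <- rowSums(w)
  p <- rep(0, nrow(w))
  for (com in unique(membership)) {
    k_com <- rowSums(w[, membership == com, drop = FALSE])
    nz <- k > 0
    p[nz] <- p[nz] + (k_com[nz] / k[nz])^2
  }
  ifelse(k > 0, 1 - p, 0)
}

# weighted rich-club curve: for each degree level k, the total weight
# among nodes of degree > k relative to the same number of strongest
# weights anywhere in the network
rich_club_curve <- function(w) {
  deg <- colSums(w > 0)
  if (max(deg) < 1) return(numeric(0))
  ut_vals <- w[upper.tri(w)]
  wrank <- sort(ut_vals[ut_vals > 0], decreasing = TRUE)
  vapply(seq_len(max(deg)), function(kk) {
    keep <- deg > kk
    if (sum(keep) < 2) return(NA_real_)
    sub <- w[keep, keep, drop = FALSE]
    e_r <- sum(sub[upper.tri(sub)] > 0)
    if (e_r == 0) return(NA_real_)
    sum(sub[upper.tri(sub)]) / sum(wrank[seq_len(e_r)])
  }, numeric(1))
}

#' Graph-topology feature set for one subject
#'
#' Computes the eight weighted-graph measures used as classifier
#' features, two per topological domain: centrality (mean node strength,
#' mean eigenvector centrality), integration (characteristic path length
#' with edge length 1/weight, mean first-passage time of the random walk
#' on the largest connected component), segregation (Louvain modularity
#' of the best partition, mean participation coefficient against that
#' partition), and network organization (weighted degree assortativity,
#' mean of the weighted rich-club curve over defined degree levels).
#'
#' @param g a [weighted_graph()] with at least 2 nodes and 1 edge.
#' @param rc_mode scalarization of the rich-club curve: `"mean"`
#'   (default) or `"max"`.
#' @param community_seed RNG seed for the Louvain partition (fixed by
#'   default so features are deterministic).
#' @return one-row data.frame with columns `strength_mean`,
#'   `eigenvector_centrality_mean`, `characteristic_path_length`,
#'   `mean_first_passage_time`, `modularity_q`,
#'   `participation_coefficient_mean`, `assortativity`,
#'   `rich_club_coefficient`.
#' @export
compute_graph_features <- function(g, rc_mode = c("mean", "max"),
                                   community_seed = 42) {
  rc_mode <- match.arg(rc_mode)
  stopifnot(inherits(g, "weighted_graph"))
  w <- g$weights
  n <- nrow(w)
  if (n < 2) stop_brainfp("graph needs at least 2 nodes")
  if (all(w == 0)) stop_brainfp("graph has no edges")

  strength <- rowSums(w)
  strength_mean <- mean(strength)
  eig <- principal_eigenvector(w)
  eig_mean <- mean(eig)

  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(ig)$weight
  d <- igraph::distances(ig, weights = len)
  finite_off <- is.finite(d) & row(d) != col(d)
  if (!all(is.finite(d[row(d) != col(d)]))) {
    warning("graph is disconnected; path length restricted to connected pairs")
  }
  cpl <- mean(d[finite_off])

  comp <- igraph::components(ig)
  biggest <- which.max(comp$csize)
  in_big <- comp$membership == biggest
  mfpt <- if (sum(in_big) >= 2) {
    m <- mfpt_matrix(w[in_big, in_big, drop = FALSE])
    mean(m[row(m) != col(m)])
  } else {
    NA_real_
  }

  comm <- with_seed(community_seed, igraph::cluster_louvain(ig))
  membership <- igraph::membership(comm)
  q <- igraph::modularity(ig, membership, weights = igraph::E(ig)$weight)
  pc <- mean(participation_coefficient(w, membership))

  assort <- assortativity_weighted(w)
  rc <- rich_club_curve(w)
  rc <- rc[is.finite(rc)]
  rc_val <- if (length(rc) == 0) NA_real_ else
    if (rc_mode == "mean") mean(rc) else max(rc)

  data.frame(
    strength_mean = strength_mean,
    eigenvector_centrality_mean = eig_mean,
    characteristic_path_length = cpl,
    mean_first_passage_time = mfpt,
    modularity_q = q,
    participation_coefficient_mean = pc,
    assortativity = assort,
    rich_club_coefficient = rc_val
  )
}

# weighted degree (strength) assortativity over edges, Pearson-style
# formula on the endpoint strengths of each edge
assortativity_weighted <- function(w) {
  strength <- rowSums(w)
  ut <- upper.tri(w)
  sel <- which(ut & w > 0, arr.ind = TRUE)
  if (nrow(sel) < 2) return(NA_real_)
  si <- strength[sel[, 1]]
  sj <- strength[sel[, 2]]
  k <- nrow(sel)
  num <- sum(si * sj) / k - (sum(0.5 * (si + sj)) / k)^2
  den <- sum(0.5 * (si^2 + sj^2)) / k - (sum(0.5 * (si + sj)) / k)^2
  if (den == 0) return(NA_real_)
  num / den
}

#' Feature table across subjects
#'
#' Convenience wrapper building the subjects x 8 feature table from a
#' list of per-subject graphs.
#'
#' @param graphs named list of [weighted_graph()] objects.
#' @param ... passed to [compute_graph_features()].
#' @return data.frame, one row per subject.
#' @export
graph_feature_table <- function(graphs, ...) {
  rows <- lapply(graphs, compute_graph_features, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- names(graphs)
  out
}
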