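#' Parcellated BOLD time series for one subject
#'
#' Light container for a subject's time-by-region signal matrix, the raw
#' input of the fingerprinting pipeline.
#'
#' @param subject_id subject identifier (string).
#' @param group `"control"` or `"patient"`.
#' @param data numeric matrix, rows = time points, columns = regions.
#' @param region_ids ordered region identifiers; defaults to column names
#'   or `"R001"..`.
#' @return an object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(subject_id, group, data, region_ids = NULL) {
  group <- match.arg(group, c("control", "patient"))
  data <- as.matrix(data)
  if (anyNA(data)) {
    stop_brainfp("time series for subject '%s' contains missing values", subject_id)
  }
  if (is.null(region_ids)) {
    region_ids <- colnames(data) %||% sprintf("R%03d", seq_len(ncol(data)))
  }
  if (length(region_ids) != ncol(data)) {
    stop_brainfp("region_ids length (%d) does not match region count (%d)",
                 length(region_ids), ncol(data))
  }
  colnames(data) <- region_ids
  structure(
    list(subject_id = as.character(subject_id), group = group,
         data = data, region_ids = as.character(region_ids)),
    class = "parcellated_ts"
  )
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("<parcellated_ts> subject %s (%s): %d time points x %d regions\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Edge index for the vectorized upper triangle
#'
#' Enumerates the R(R-1)/2 region pairs (i < j) in row-major order, the
#' single edge ordering shared by every stage of the pipeline (test/retest
#' vectors, ICC maps, masks).
#'
#' @param n_regions number of regions R.
#' @return data.frame with integer columns `i`, `j` (1-based) and `edge`
#'   (position in the vectorized profile).
#' @export
edge_index <- function(n_regions) {
  if (n_regions < 2) stop_brainfp("need at least 2 regions, got %d", n_regions)
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(k) (k + 1L):n_regions),
              use.names = FALSE)
  data.frame(edge = seq_along(i), i = i, j = j)
}

# Logical index selecting the row-major upper triangle of an R x R matrix.
# For a matrix m, m[upper_tri_rowmajor(R)] walks edges (1,2),(1,3),...,(2,3),...
upper_tri_rowmajor <- function(n_regions) {
  idx <- edge_index(n_regions)
  (idx$j - 1L) * n_regions + idx$i
}

#' Split-half functional connectomes
#'
#' Splits a subject's time series into first and second halves (first half
#' gets `floor(T/2)` samples) and computes a Pearson correlation matrix per
#' half, yielding the test/retest connectome pair that the fingerprinting
#' analysis is built on.
#'
#' @param ts a [parcellated_ts()] object.
#' @return object of class `connectome_pair` with elements `subject_id`,
#'   `group`, `fc_test`, `fc_retest`, `region_ids`.
#' @export
compute_split_fc <- function(ts) {
  stopifnot(inherits(ts, "parcellated_ts"))
  x <- ts$data
  n_t <- nrow(x)
  if (n_t < 4) stop_brainfp("need at least 4 time points, got %d", n_t)
  t1 <- seq_len(n_t %/% 2L)
  halves <- list(test = x[t1, , drop = FALSE],
                 retest = x[-t1, , drop = FALSE])
  fc <- lapply(names(halves), function(h) {
    m <- halves[[h]]
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      bad <- ts$region_ids[sds == 0]
      stop_brainfp("constant region(s) in %s half of subject '%s': %s",
                   h, ts$subject_id, paste(bad, collapse = ", "))
    }
    cc <- stats::cor(m)
    diag(cc) <- 1
    cc
  })
  names(fc) <- names(halves)
  structure(
    list(subject_id = ts$subject_id, group = ts$group,
         fc_test = fc$test, fc_retest = fc$retest,
         region_ids = ts$region_ids),
    class = "connectome_pair"
  )
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the upper-triangle (i < j) entries in row-major order, the edge
#' ordering defined by [edge_index()].
#'
#' @param fc symmetric numeric matrix.
#' @param tol symmetry tolerance (default 1e-8).
#' @return numeric vector of length R(R-1)/2.
#' @export
vectorize_fc <- function(fc, tol = 1e-8) {
  fc <- as.matrix(fc)
  if (nrow(fc) != ncol(fc)) stop_brainfp("matrix is not square")
  if (max(abs(fc - t(fc)), na.rm = TRUE) > tol) {
    stop_brainfp("matrix is asymmetric beyond tolerance %g", tol)
  }
  fc[upper_tri_rowmajor(nrow(fc))]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_fc()]; the diagonal is set to `diag_value`.
#'
#' @param values edge vector of length R(R-1)/2.
#' @param diag_value diagonal fill (1 for correlation matrices, `NA` for
#'   ICC maps whose diagonal is undefined).
#' @return R x R symmetric matrix.
#' @export
devectorize_fc <- function(values, diag_value = 1) {
  e <- length(values)
  r <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(r - round(r)) > 1e-9) {
    stop_brainfp("length %d is not a valid edge count R(R-1)/2", e)
  }
  r <- as.integer(round(r))
  m <- matrix(diag_value, r, r)
  m[upper_tri_rowmajor(r)] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Stack per-subject edge vectors into a subjects-by-edges matrix
#'
#' @param pairs list of `connectome_pair` objects.
#' @param half `"test"` or `"retest"`.
#' @return numeric matrix, one row per subject (rownames = subject ids).
#' @export
edge_matrix <- function(pairs, half = c("test", "retest")) {
  half <- match.arg(half)
  fld <- paste0("fc_", half)
  out <- t(vapply(pairs, function(p) vectorize_fc(p[[fld]]),
                  numeric(length(upper_tri_rowmajor(nrow(pairs[[1]][[fld]]))))))
  rownames(out) <- vapply(pairs, `[[`, character(1), "subject_id")
  out
}

#' Residualize edge values against covariates
#'
#' Fits, at every edge, an ordinary least-squares regression of the edge
#' value on the covariates (plus intercept) across subjects, and returns
#' the residuals. Covariate columns that are constant in the supplied table
#' (e.g. disease duration among controls, which is zero-filled by
#' construction) are dropped before fitting. Residuals have zero mean
#' across subjects at every edge and the intercept is not added back.
#'
#' @param edges subjects x edges numeric matrix (rownames = subject ids).
#' @param covariates data.frame with `subject_id` plus numeric covariate
#'   columns; rows are matched to `edges` by subject id.
#' @param covariate_cols covariate columns to use; defaults to
#'   age, sex, education, disease_duration, onset_age when present.
#' @return matrix of residuals with the same dimensions as `edges`.
#' @export
residualize_edges <- function(edges, covariates,
                              covariate_cols = NULL) {
  stopifnot(is.matrix(edges))
  if (is.null(covariate_cols)) {
    covariate_cols <- intersect(
      c("age", "sex", "education", "disease_duration", "onset_age"),
      names(covariates))
  }
  if (is.null(rownames(edges))) {
    stop_brainfp("edge matrix must carry subject ids as rownames")
  }
  ord <- match(rownames(edges), covariates$subject_id)
  if (anyNA(ord)) {
    stop_brainfp("covariate table is missing subjects: %s",
                 paste(rownames(edges)[is.na(ord)], collapse = ", "))
  }
  x <- as.matrix(covariates[ord, covariate_cols, drop = FALSE])
  if (anyNA(x)) stop_brainfp("covariates contain missing values")
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  x <- x[, keep, drop = FALSE]
  design <- cbind(`(Intercept)` = 1, x)
  if (nrow(edges) < ncol(design) + 2) {
    stop_brainfp("need at least %d subjects for %d covariate columns",
                 ncol(design) + 2, ncol(design) - 1)
  }
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    bad <- colnames(design)[qx$pivot[(qx$rank + 1):ncol(design)]]
    stop_brainfp("rank-deficient covariate design; collinear columns: %s",
                 paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, edges)
  dimnames(res) <- dimnames(edges)
  res
}
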