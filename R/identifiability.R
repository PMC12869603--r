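#' Build the identifiability matrix
#'
#' Correlates every subject's test connectivity profile with every
#' subject's retest profile. Entry `m[s, i]` is the Pearson correlation
#' between subject s's test edge vector and subject i's retest edge
#' vector; the diagonal therefore holds each subject's self-similarity.
#'
#' @param test,retest subjects x edges matrices with identical subject
#'   order (rownames) and edge count.
#' @return object of class `ident_matrix`: list with `m` (N x N matrix)
#'   and `subject_order`.
#' @export
build_identifiability_matrix <- function(test, retest) {
  stopifnot(is.matrix(test), is.matrix(retest))
  if (!identical(dim(test), dim(retest))) {
    stop_brainfp("test and retest matrices must share dimensions")
  }
  if (!identical(rownames(test), rownames(retest))) {
    stop_brainfp("test and retest matrices must share subject order")
  }
  sd_t <- apply(test, 1, stats::sd)
  sd_r <- apply(retest, 1, stats::sd)
  if (any(sd_t == 0) || any(sd_r == 0)) {
    bad <- unique(c(rownames(test)[sd_t == 0], rownames(retest)[sd_r == 0]))
    stop_brainfp("zero-variance connectivity profile for subject(s): %s",
                 paste(bad, collapse = ", "))
  }
  m <- stats::cor(t(test), t(retest))
  dimnames(m) <- list(rownames(test), rownames(test))
  structure(list(m = m, subject_order = rownames(test)),
            class = "ident_matrix")
}

#' @export
print.ident_matrix <- function(x, ...) {
  cat(sprintf("<ident_matrix> %d subjects; mean diag %.3f, mean off-diag %.3f\n",
              nrow(x$m), mean(diag(x$m)),
              mean(x$m[row(x$m) != col(x$m)])))
  invisible(x)
}

#' Identifiability metrics from an identifiability matrix
#'
#' Computes the fingerprinting summary metrics: per-subject self-similarity
#' (diagonal), per-subject similarity to others (average of the 2N-2
#' off-diagonal entries in that subject's row and column), their mean
#' difference `i_diff`, the pooled-SD standardized version `i_diff_norm`
#' (within set = N diagonal entries, between set = N^2 - N off-diagonal
#' entries), and the identification success rate SR: the percentage of
#' subjects whose self-similarity strictly exceeds every competing
#' cross-subject similarity.
#'
#' @param im an `ident_matrix` (or plain square matrix).
#' @param match_scope `"both"` compares the diagonal against both the row
#'   and the column off-diagonals (default); `"row"` against the row only.
#' @return object of class `ident_metrics`: list with `i_self`,
#'   `i_others` (named per subject), scalars `i_diff`, `i_diff_norm`,
#'   `sr` (percent), and `match_scope`.
#' @export
compute_identifiability_metrics <- function(im, match_scope = c("both", "row")) {
  match_scope <- match.arg(match_scope)
  m <- if (inherits(im, "ident_matrix")) im$m else as.matrix(im)
  n <- nrow(m)
  if (n < 2) stop_brainfp("need at least 2 subjects, got %d", n)
  off <- row(m) != col(m)
  i_self <- diag(m)
  i_others <- vapply(seq_len(n), function(s) {
    (sum(m[s, -s]) + sum(m[-s, s])) / (2 * n - 2)
  }, numeric(1))
  names(i_others) <- names(i_self) <- rownames(m)
  within <- i_self
  between <- m[off]
  v_w <- stats::var(within)
  v_b <- stats::var(between)
  pooled <- sqrt(((length(within) - 1) * v_w + (length(between) - 1) * v_b) /
                   (length(within) + length(between) - 2))
  if (pooled == 0) stop_brainfp("degenerate identifiability distribution")
  i_diff <- mean(i_self) - mean(i_others)
  i_diff_norm <- (mean(within) - mean(between)) / pooled
  hit <- vapply(seq_len(n), function(s) {
    competitors <- if (match_scope == "both") c(m[s, -s], m[-s, s]) else m[s, -s]
    all(m[s, s] > competitors)
  }, logical(1))
  structure(
    list(i_self = i_self, i_others = i_others, i_diff = i_diff,
         i_diff_norm = i_diff_norm, sr = 100 * mean(hit),
         match_scope = match_scope),
    class = "ident_metrics"
  )
}

#' @export
print.ident_metrics <- function(x, ...) {
  cat(sprintf(paste0("<ident_metrics> mean I_self %.3f, mean I_others %.3f, ",
                     "I_diff %.3f, I_diff-norm %.2f, SR %.1f%%\n"),
              mean(x$i_self), mean(x$i_others), x$i_diff, x$i_diff_norm, x$sr))
  invisible(x)
}

# i_diff_norm of a plain matrix (used inside the bootstrap loops)
idiff_norm_of <- function(m) {
  within <- diag(m)
  between <- m[row(m) != col(m)]
  pooled <- sqrt(((length(within) - 1) * stats::var(within) +
                    (length(between) - 1) * stats::var(between)) /
                   (length(within) + length(between) - 2))
  if (pooled == 0) return(NA_real_)
  (mean(within) - mean(between)) / pooled
}

#' Bootstrap inference for normalized differential identifiability
#'
#' Resamples subject indices with replacement (1000 iterations by
#' default) and recomputes the normalized differential identifiability
#' from the resampled subject-level values each time: the within set is
#' the resampled subjects' self-similarities and the between set their
#' per-subject mean similarity to others, standardized by the pooled SD.
#' (Resampling subject-level summaries rather than matrix rows avoids
#' the artifact where a duplicated subject's self-similarity lands in
#' the between set.) With a single matrix the bootstrap distribution of
#' the index itself is returned; with two matrices the difference
#' `m_b - m_a` is bootstrapped, either independently per matrix or — in
#' paired mode, for comparing two versions of the same cohort (e.g. raw
#' vs residualized) — by applying identical index draws to both
#' matrices.
#'
#' @param m_a an `ident_matrix`.
#' @param m_b optional second `ident_matrix`.
#' @param paired apply the same resampled indices to both matrices
#'   (requires identical subject order).
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @return object of class `bootstrap_result`: `estimate`, `ci_low`,
#'   `ci_high` (2.5th/97.5th percentiles), `p_value` (empirical
#'   two-tailed, only for difference comparisons), `n_iter`, `seed`,
#'   `paired`, and the bootstrap `draws`.
#' @export
bootstrap_idiff_norm <- function(m_a, m_b = NULL, paired = FALSE,
                                 n_iter = 1000, seed = 1) {
  stopifnot(inherits(m_a, "ident_matrix"))
  if (n_iter < 100) warning("n_iter < 100: bootstrap p-values will be coarse")
  if (!is.null(m_b)) {
    stopifnot(inherits(m_b, "ident_matrix"))
    if (paired && !identical(m_a$subject_order, m_b$subject_order)) {
      stop_brainfp("paired bootstrap requires identical subject order")
    }
  } else if (paired) {
    stop_brainfp("paired mode requires two matrices")
  }
  n_a <- nrow(m_a$m)
  subject_sets <- function(im) {
    n <- nrow(im$m)
    list(i_self = diag(im$m),
         i_others = vapply(seq_len(n), function(s) {
           (sum(im$m[s, -s]) + sum(im$m[-s, s])) / (2 * n - 2)
         }, numeric(1)))
  }
  idn_subject <- function(sets, idx) {
    within <- sets$i_self[idx]
    between <- sets$i_others[idx]
    pooled <- sqrt(((length(within) - 1) * stats::var(within) +
                      (length(between) - 1) * stats::var(between)) /
                     (length(within) + length(between) - 2))
    if (pooled == 0) return(NA_real_)
    (mean(within) - mean(between)) / pooled
  }
  sets_a <- subject_sets(m_a)
  sets_b <- if (!is.null(m_b)) subject_sets(m_b) else NULL
  draws <- with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      idx_a <- sample.int(n_a, n_a, replace = TRUE)
      if (is.null(m_b)) {
        idn_subject(sets_a, idx_a)
      } else if (paired) {
        idn_subject(sets_b, idx_a) - idn_subject(sets_a, idx_a)
      } else {
        n_b <- nrow(m_b$m)
        idx_b <- sample.int(n_b, n_b, replace = TRUE)
        idn_subject(sets_b, idx_b) - idn_subject(sets_a, idx_a)
      }
    }, numeric(1))
  })
  draws <- draws[is.finite(draws)]
  estimate <- if (is.null(m_b)) {
    idn_subject(sets_a, seq_len(n_a))
  } else {
    idn_subject(sets_b, seq_len(nrow(m_b$m))) -
      idn_subject(sets_a, seq_len(n_a))
  }
  ci <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  p_value <- NA_real_
  if (!is.null(m_b)) {
    # empirical two-tailed p for H0: difference = 0, against the
    # bootstrap distribution centred at its mean
    ctr <- mean(draws)
    p_value <- (1 + sum(abs(draws - ctr) >= abs(0 - ctr))) /
      (length(draws) + 1)
  }
  structure(
    list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
         p_value = p_value, n_iter = n_iter, seed = seed, paired = paired,
         draws = draws),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> estimate %.3f [%.3f, %.3f], p = %s (%d iter)\n",
              x$estimate, x$ci_low, x$ci_high,
              ifelse(is.na(x$p_value), "n.a.", format.pval(x$p_value)),
              x$n_iter))
  invisible(x)
}
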