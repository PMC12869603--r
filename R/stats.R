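#' Normality-gated group comparison
#'
#' Compares two samples the way clinical summaries are usually built:
#' Shapiro-Wilk normality is assessed first (on the paired differences
#' for paired comparisons, on each sample otherwise, gate at
#' `p < alpha`); normal data get a t-test, non-normal data the matching
#' rank test (Wilcoxon signed-rank when paired, Mann-Whitney U
#' otherwise). Categorical inputs (factors or characters) are compared
#' with a chi-square test on the contingency table. For numeric
#' comparisons the 95% confidence interval of the mean difference is
#' always derived from the t distribution, and Cohen's d uses the SD of
#' the differences (paired) or the pooled SD (independent).
#'
#' @param x,y the two samples (numeric, or factor/character for
#'   categorical data).
#' @param paired paired comparison (requires equal lengths).
#' @param alpha normality-gate level (default 0.05).
#' @return object of class `comparison_result`: `test_name`,
#'   `statistic`, `p_value`, `effect_size`, `ci`, `n`, `df`.
#' @export
compare_groups <- function(x, y, paired = FALSE, alpha = 0.05) {
  if ((is.factor(x) || is.character(x)) && (is.factor(y) || is.character(y))) {
    lev <- sort(unique(c(as.character(x), as.character(y))))
    tab <- rbind(table(factor(x, levels = lev)), table(factor(y, levels = lev)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(comparison_result("chi_square", unname(ct$statistic), ct$p.value,
                             NA_real_, c(NA_real_, NA_real_),
                             c(length(x), length(y)), unname(ct$parameter)))
  }
  if (length(x) < 3 || length(y) < 3) {
    stop_brainfp("need at least 3 observations per sample")
  }
  if (paired) {
    if (length(x) != length(y)) stop_brainfp("paired samples must have equal length")
    d <- x - y
    n <- length(d)
    if (all(d == 0)) {
      return(comparison_result("paired_t", 0, 1, 0, c(0, 0), n, n - 1))
    }
    normal <- stats::shapiro.test(d)$p.value >= alpha
    ci <- mean(d) + c(-1, 1) * stats::qt(0.975, n - 1) * stats::sd(d) / sqrt(n)
    eff <- mean(d) / stats::sd(d)
    if (normal) {
      tt <- stats::t.test(x, y, paired = TRUE)
      comparison_result("paired_t", unname(tt$statistic), tt$p.value,
                        eff, ci, n, unname(tt$parameter))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      comparison_result("wilcoxon_signed_rank", unname(wt$statistic),
                        wt$p.value, eff, ci, n, NA_real_)
    }
  } else {
    const_x <- stats::sd(x) == 0
    const_y <- stats::sd(y) == 0
    normal <- !const_x && !const_y &&
      stats::shapiro.test(x)$p.value >= alpha &&
      stats::shapiro.test(y)$p.value >= alpha
    if (normal) {
      sp <- sqrt(((length(x) - 1) * stats::var(x) +
                    (length(y) - 1) * stats::var(y)) /
                   (length(x) + length(y) - 2))
      if (sp == 0) stop_brainfp("zero variance where a t-test is selected")
      tt <- stats::t.test(x, y, var.equal = TRUE)
      comparison_result("independent_t", unname(tt$statistic), tt$p.value,
                        (mean(x) - mean(y)) / sp, as.numeric(tt$conf.int),
                        c(length(x), length(y)), unname(tt$parameter))
    } else {
      if (const_x && const_y && length(unique(c(x, y))) == 1) {
        return(comparison_result("mann_whitney_u", NA_real_, 1, 0, c(0, 0),
                                 c(length(x), length(y)), NA_real_))
      }
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      df <- length(x) + length(y) - 2
      sp <- sqrt(((length(x) - 1) * stats::var(x) +
                    (length(y) - 1) * stats::var(y)) / df)
      se <- sp * sqrt(1 / length(x) + 1 / length(y))
      ci <- (mean(x) - mean(y)) + c(-1, 1) * stats::qt(0.975, df) * se
      eff <- if (sp > 0) (mean(x) - mean(y)) / sp else NA_real_
      comparison_result("mann_whitney_u", unname(wt$statistic), wt$p.value,
                        eff, ci, c(length(x), length(y)), NA_real_)
    }
  }
}

comparison_result <- function(test_name, statistic, p_value, effect_size,
                              ci, n, df) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, effect_size = effect_size,
                 ci = ci, n = n, df = df),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, p = %.4g, d = %.3g\n",
              x$test_name, x$statistic, x$p_value, x$effect_size))
  invisible(x)
}

#' Reconstruct a paired t statistic from printed summaries
#'
#' Given a reported mean change with its 95% confidence interval and the
#' sample size, recovers the implied standard error
#' `SE = (ci_high - ci_low) / (2 t_crit(0.975, n - 1))` and the t
#' statistic `|mean_diff| / SE` — a consistency check for published
#' summary tables.
#'
#' @param mean_diff reported mean difference.
#' @param ci_low,ci_high reported 95% CI bounds.
#' @param n sample size.
#' @return the implied |t| statistic.
#' @export
t_from_summary <- function(mean_diff, ci_low, ci_high, n) {
  if (!is_scalar_number(ci_low) || !is_scalar_number(ci_high) ||
      ci_low >= ci_high) {
    stop_brainfp("degenerate confidence interval")
  }
  if (n < 2) stop_brainfp("n must be >= 2")
  se <- (ci_high - ci_low) / (2 * stats::qt(0.975, n - 1))
  abs(mean_diff) / se
}
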