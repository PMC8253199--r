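#' Repeated-measures correlation
#'
#' Estimates the common within-subject linear association between two
#' repeatedly measured variables by the analysis-of-covariance model
#' `y ~ subject + common slope * x`: subject means are absorbed as fixed
#' effects, and the correlation is
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))`, which equals the
#' Pearson correlation of the within-subject-centered values. Degrees of
#' freedom are `n_obs - n_subjects - 1` and the p-value comes from the t
#' distribution on that df. Unlike a naive pooled correlation, `r_rm` is
#' unaffected by between-subject level differences.
#'
#' @param x,y paired numeric vectors.
#' @param subject subject labels, same length as `x`.
#' @return object of class `rmcorr_result`: list with `r_rm`, `df`,
#'   `p_value`, `n_subjects`, `n_obs`, `slope`.
#' @export
rmcorr <- function(x, y, subject) {
  if (length(x) != length(y) || length(x) != length(subject)) {
    stop_("`x`, `y` and `subject` must have equal length")
  }
  assert_flag_finite(x, "x"); assert_flag_finite(y, "y")
  g <- as.factor(subject)
  sizes <- tabulate(g)
  if (nlevels(g) < 2L) stop_("at least 2 subjects required")
  if (any(sizes < 2L)) {
    stop_("every subject needs >= 2 observations (subject '%s' has %d)",
          levels(g)[which.min(sizes)], min(sizes))
  }
  xc <- x - ave(x, g)
  yc <- y - ave(y, g)
  ssx <- sum(xc^2)
  if (ssx < 1e-12 * length(x)) {
    stop_("a subject-centered `x` is (numerically) constant; slope not identified")
  }
  slope <- sum(xc * yc) / ssx
  ss_measure <- slope^2 * ssx
  ss_error <- sum(yc^2) - ss_measure
  df <- length(x) - nlevels(g) - 1L
  if (df < 3L) stop_("fewer than 3 residual degrees of freedom (df = %d)", df)
  r <- sign(slope) * sqrt(ss_measure / (ss_measure + ss_error))
  r <- max(min(r, 1), -1)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  structure(list(r_rm = r, df = df, p_value = p,
                 n_subjects = nlevels(g), n_obs = length(x), slope = slope),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("Repeated-measures correlation: r_rm = %.4f (df = %d, p = %.4g; %d subjects, %d obs)\n",
              x$r_rm, x$df, x$p_value, x$n_subjects, x$n_obs))
  invisible(x)
}

#' Approximate Fisher-z confidence interval for a repeated-measures correlation
#'
#' @param result an [rmcorr()] result.
#' @param level confidence level.
#' @return length-2 numeric vector (lower, upper). Labeled approximate: the
#'   Fisher transform treats `df` as an effective sample size.
#' @export
rmcorr_ci <- function(result, level = 0.95) {
  stopifnot(inherits(result, "rmcorr_result"))
  z <- atanh(result$r_rm)
  se <- 1 / sqrt(result$df - 1)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Kruskal-Wallis test with Bonferroni-corrected pairwise follow-ups
#'
#' Omnibus rank-based comparison of two or more groups (tie-corrected H
#' statistic, chi-square reference on `k - 1` df, via
#' [stats::kruskal.test()]), followed by all pairwise two-group rank tests
#' whose p-values are multiplied by the comparison-family size and capped
#' at 1. The family size is an explicit argument because the appropriate
#' family depends on the analysis design; it defaults to the number of
#' pairwise group comparisons actually performed, and the value used is
#' echoed in the result.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @param n_comparisons Bonferroni family size; default
#'   `choose(length(groups), 2)`.
#' @return list with `H`, `df`, `p_value`, and `pairwise` (data.frame:
#'   `group1`, `group2`, `p_raw`, `p_bonferroni`, `n_comparisons`).
#' @export
kruskal_wallis_bonferroni <- function(groups, n_comparisons = NULL) {
  if (!is.list(groups) || length(groups) < 2L) stop_("need a list of >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop_("every group needs >= 2 values (group %d has %d)",
                             which.min(sizes), min(sizes))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  pairs <- utils::combn(seq_along(groups), 2L)
  n_comparisons <- n_comparisons %||% ncol(pairs)
  pw <- apply(pairs, 2L, function(ij) {
    sub <- stats::kruskal.test(groups[ij])
    sub$p.value
  })
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             p_raw = pw,
             p_bonferroni = pmin(pw * n_comparisons, 1),
             n_comparisons = n_comparisons,
             stringsAsFactors = FALSE) -> pairwise
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairwise = pairwise)
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector with at least 2 values.
#' @return named numeric vector `c(mean, sem)` with
#'   `sem = sd(values) / sqrt(n)`.
#' @export
mean_sem <- function(values) {
  assert_flag_finite(values, "values")
  n <- length(values)
  if (n < 2L) stop_("need at least 2 values")
  c(mean = mean(values), sem = stats::sd(values) / sqrt(n))
}
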