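# Rank-based statistics for method comparison: the Brunner-Munzel
# independence test, a paired-rank variant for per-repeat paired designs,
# Bonferroni adjustment of the significance level, and the Kendall trend
# test between circular-fingerprint radius and accuracy.

#' Brunner-Munzel test
#'
#' Nonparametric test of the relative effect p = P(X < Y) + 0.5 P(X = Y)
#' against 1/2.  The independent-samples form uses the Brunner-Munzel
#' studentized rank statistic with Satterthwaite degrees of freedom; the
#' paired form studentizes the mean combined-rank difference across pairs
#' (paired rank test for the relative treatment effect).
#'
#' @param x,y numeric samples (equal length when `paired = TRUE`)
#' @param alternative `"two.sided"`, `"less"` (p < 1/2), or `"greater"`
#' @param paired use the paired-rank form
#' @return list with `statistic`, `df`, `p.value`, `estimate` (the relative
#'   effect), and `degenerate` (TRUE when all values are tied and the
#'   variance vanishes)
#' @export
brunner_munzel <- function(x, y, alternative = c("two.sided", "less",
                                                 "greater"),
                           paired = FALSE) {
  alternative <- match.arg(alternative)
  if (paired && length(x) != length(y))
    stop("paired samples must have equal length")
  if (!paired) {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
    m1 <- mean(r1); m2 <- mean(r2)
    p_hat <- (m2 - (n2 + 1) / 2) / n1
    v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
    v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
    if (v1 == 0 && v2 == 0)
      return(.bm_degenerate(p_hat, alternative))
    se <- sqrt(n1 * v1 + n2 * v2) * (n1 + n2) / (n1 * n2)
    stat <- (m2 - m1) / se
    df <- (n1 * v1 + n2 * v2)^2 /
      ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  } else {
    n <- length(x)
    r <- rank(c(x, y))
    z <- r[n + seq_len(n)] - r[seq_len(n)]
    p_hat <- 0.5 + mean(z) / (2 * n)
    s <- stats::sd(z)
    if (s == 0)
      return(.bm_degenerate(p_hat, alternative))
    stat <- sqrt(n) * mean(z) / s
    df <- n - 1
  }
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(stat), df),
              greater = stats::pt(stat, df, lower.tail = FALSE),
              less = stats::pt(stat, df))
  list(statistic = stat, df = df, p.value = p, estimate = p_hat,
       degenerate = FALSE)
}

# Zero-variance cases: all values tied (relative effect 1/2) or completely
# separated supports (relative effect 0 or 1).  The statistic is flagged
# degenerate; the P value is the limiting one (1 for identical samples,
# the double floor for full separation in the concordant direction).
.bm_degenerate <- function(p_hat, alternative) {
  floor_p <- .Machine$double.xmin
  p <- if (isTRUE(all.equal(p_hat, 0.5))) {
    if (alternative == "two.sided") 1 else 0.5
  } else if (p_hat > 0.5) {
    switch(alternative, two.sided = floor_p, greater = floor_p, less = 1)
  } else {
    switch(alternative, two.sided = floor_p, less = floor_p, greater = 1)
  }
  list(statistic = if (isTRUE(all.equal(p_hat, 0.5))) NA_real_ else
    sign(p_hat - 0.5) * Inf,
    df = NA_real_, p.value = p, estimate = p_hat, degenerate = TRUE)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise error rate (default 0.05)
#' @param n_comparisons number of comparisons (e.g. 17 methods)
#' @return per-comparison significance level `alpha / n_comparisons`
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_comparisons) {
  alpha / n_comparisons
}

#' Compare two methods' per-repeat accuracies
#'
#' @param acc_a,acc_b numeric vectors of per-repeat correct-match fractions
#' @param paired treat repeats as paired (same libraries; the default)
#' @param alternative test direction, as in [brunner_munzel()]
#' @return the [brunner_munzel()] result
#' @export
compare_methods <- function(acc_a, acc_b, paired = TRUE,
                            alternative = "two.sided") {
  brunner_munzel(acc_a, acc_b, alternative = alternative, paired = paired)
}

#' Kendall trend between circular-fingerprint radius and accuracy
#'
#' Pools per-repeat accuracies of the circular fingerprints (both families)
#' and computes the Kendall rank correlation (tau-b) between radius and
#' accuracy.
#'
#' @param accuracy data frame with columns `method` and `fraction` (one row
#'   per method and repeat), as produced by [accuracy_summary()]
#' @param exclude_radius0 drop the radius-0 members before testing
#' @return list with `tau`, `p.value`, and `n`
#' @export
radius_accuracy_trend <- function(accuracy, exclude_radius0 = FALSE) {
  radii <- vapply(accuracy$method, function(m) {
    entry <- .fp_registry[[m]]
    if (is.null(entry) || is.null(entry$meta$radius)) NA_integer_
    else entry$meta$radius
  }, 1L)
  keep <- !is.na(radii)
  if (exclude_radius0) keep <- keep & radii > 0L
  x <- radii[keep]; y <- accuracy$fraction[keep]
  if (length(unique(x)) < 2L)
    stop("need accuracies for at least two circular-fingerprint radii")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}
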