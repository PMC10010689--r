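#' Select the two-group test by normality and variance screening
#'
#' The comparison rule used for all two-group readouts: each group is
#' screened with the Shapiro-Wilk normality test and the pair with the
#' two-sided F-ratio (Fisher) variance test; the unpaired Student t-test is
#' chosen if and only if all three preliminary p-values exceed `alpha`,
#' otherwise the Mann-Whitney (Wilcoxon rank-sum) test is used. The
#' screening already enforces variance homogeneity, so the equal-variance
#' form of the t-test applies when selected.
#'
#' @param a,b numeric vectors, at least 3 values each (Shapiro-Wilk is
#'   undefined below that).
#' @param alpha screening level for the preliminary tests.
#' @return a `test_choice` list: `chosen_test` ("unpaired-t" or
#'   "mann-whitney"), `normality_p_a`, `normality_p_b`, `variance_p`,
#'   `alpha`.
#' @export
choose_test <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 values for the normality screen")
  }
  # a constant sample is degenerate for Shapiro-Wilk (and trivially not
  # Gaussian-compatible): it fails the screen by convention
  pa <- if (stats::sd(a) == 0) 0 else stats::shapiro.test(a)$p.value
  pb <- if (stats::sd(b) == 0) 0 else stats::shapiro.test(b)$p.value
  pf <- if (stats::sd(a) == 0 && stats::sd(b) == 0) 0 else
    stats::var.test(a, b)$p.value
  structure(list(chosen_test = decision_from_pvalues(pa, pb, pf, alpha),
                 normality_p_a = pa, normality_p_b = pb,
                 variance_p = pf, alpha = alpha),
            class = "test_choice")
}

#' @rdname choose_test
#' @param normality_p_a,normality_p_b,variance_p preliminary p-values.
#' @export
decision_from_pvalues <- function(normality_p_a, normality_p_b, variance_p,
                                  alpha = 0.05) {
  if (normality_p_a > alpha && normality_p_b > alpha && variance_p > alpha) {
    "unpaired-t"
  } else {
    "mann-whitney"
  }
}

#' Significance tier of a p-value
#'
#' The star convention used in the figures: `****` p < 0.0001, `***` p <
#' 0.001, `**` p < 0.01, `*` p < 0.05, otherwise `ns`.
#'
#' @param p p-value in [0, 1].
#' @return character tier.
#' @export
p_star_tier <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 1e-2) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Compare two groups with the screened test
#'
#' Applies [choose_test()] and runs the selected two-sided test: Student's
#' unpaired equal-variance t-test, or the Mann-Whitney rank-sum test (normal
#' approximation with continuity correction, so tied values are handled).
#'
#' @param a,b numeric vectors (>= 3 values each).
#' @param alpha screening level.
#' @return a `group_comparison` list: the `test_choice` fields plus
#'   `statistic`, `p_value`, `star`, group sizes and means.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  choice <- choose_test(a, b, alpha)
  if (choice$chosen_test == "unpaired-t") {
    ht <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  } else {
    ht <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                             correct = TRUE)
  }
  structure(c(unclass(choice),
              list(statistic = unname(ht$statistic), p_value = ht$p.value,
                   star = p_star_tier(ht$p.value),
                   n_a = length(a), n_b = length(b),
                   mean_a = mean(a), mean_b = mean(b))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: stat %.4g, p = %.3g (%s) | n = %d vs %d | screens: SW %.3g / %.3g, F %.3g (alpha %.2f)\n",
    x$chosen_test, x$statistic, x$p_value, x$star, x$n_a, x$n_b,
    x$normality_p_a, x$normality_p_b, x$variance_p, x$alpha))
  invisible(x)
}
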