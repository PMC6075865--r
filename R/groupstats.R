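## Group statistics used throughout the secretion workflows: one-way
## ANOVA with Tukey-Kramer post test, Mann-Whitney U, empirical CDFs,
## and the significance-star convention.

#' Significance stars
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `""` otherwise.
#'
#' @param p numeric p-values.
#' @return Character vector of star codes.
#' @export
significanceStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}

#' One-way ANOVA with Tukey-Kramer post test
#'
#' Omnibus one-way ANOVA followed by Tukey honest significant
#' differences; with unequal group sizes `TukeyHSD` applies the
#' Tukey-Kramer correction.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values` (at least 3
#'   groups with at least 2 observations each).
#' @return A list: `omnibus_p` (ANOVA F-test p), `pairwise` (data.frame:
#'   comparison, mean difference, adjusted p, stars).
#' @examples
#' set.seed(1)
#' v <- c(rnorm(5), rnorm(5), rnorm(5) + 5)
#' g <- rep(c("a", "b", "c"), each = 5)
#' anovaTukey(v, g)$pairwise
#' @export
anovaTukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 3) stop("need at least 3 groups")
  if (any(table(groups) < 2))
    stop("every group needs at least 2 observations")
  fit <- stats::aov(values ~ groups)
  om <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$groups
  pw <- data.frame(comparison = rownames(tk),
                   diff = tk[, "diff"],
                   p_adjusted = tk[, "p adj"],
                   stars = significanceStars(tk[, "p adj"]))
  rownames(pw) <- NULL
  list(omnibus_p = om, pairwise = pw)
}

#' Mann-Whitney U test
#'
#' Two-sided Wilcoxon rank-sum test. For small samples (both groups at
#' most `exact_max` observations, no ties) the exact distribution is
#' used; otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param a,b numeric samples.
#' @param exact_max largest per-group n for the exact test (default 8).
#' @return Two-sided p-value.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))   # exact: 0.1
#' @export
mannWhitney <- function(a, b, exact_max = 8) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  want_exact <- length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = want_exact, correct = TRUE))
  unname(wt$p.value)
}

#' Empirical cumulative distribution table
#'
#' Right-continuous step function of cumulative relative frequency at
#' the sorted unique values, rising from `1/n`-steps to exactly 1 at the
#' maximum.
#'
#' @param values non-empty numeric sample.
#' @return A `data.frame(value, cum_freq)`.
#' @examples
#' ecdfTable(c(1, 2, 3))
#' @export
ecdfTable <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  u <- sort(unique(values))
  data.frame(value = u, cum_freq = stats::ecdf(values)(u))
}
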