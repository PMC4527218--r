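#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' The two-group comparison used throughout the package's reports. The U
#' statistic comes from rank sums with midranks for ties. For small untied
#' samples (both groups at most `exact_max_n`) the exact null distribution
#' is used; otherwise a tie-corrected normal approximation with continuity
#' correction. Delegates to [stats::wilcox.test()].
#'
#' @param x,y Numeric vectors (nonempty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (for `x`
#'   versus `y`).
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) computation;
#'   default `NULL` picks exact when both groups are small and untied.
#' @param exact_max_n Exact/approximate crossover per-group size
#'   (default 20).
#' @return A one-row tibble: `statistic` (U), `p_value`, `method`,
#'   `alternative`, `n_x`, `n_y`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4), alternative = "less")  # U = 0, p = 1/6
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact = NULL, exact_max_n = 20) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be nonempty.")
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  if (sd(pooled) == 0) {
    warn("All pooled values identical; p = 1.")
    return(tibble(statistic = length(x) * length(y) / 2, p_value = 1,
                  method = "degenerate", alternative = alternative,
                  n_x = length(x), n_y = length(y)))
  }
  if (is.null(exact)) {
    exact <- !ties && length(x) <= exact_max_n && length(y) <= exact_max_n
  }
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  tibble(statistic = unname(res$statistic),
         p_value = res$p.value,
         method = if (exact && !ties) "exact" else "normal-approximation",
         alternative = alternative,
         n_x = length(x), n_y = length(y))
}

#' Bonferroni correction
#'
#' Family-wise error control for `m` simultaneous comparisons:
#' `min(1, p * m)`; order-preserving and never smaller than the input.
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @param m Number of comparisons (default `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) abort("`m` must be >= 1.")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0,1].")
  }
  pmin(1, p_values * m)
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3, nonzero variance).
#' @return The correlation coefficient in \[-1,1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero-variance input.")
  cor(x, y)
}
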