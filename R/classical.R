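#' Two-sample t-test comparator
#'
#' The classical cross-sectional comparison: difference of group means at a
#' single time point with either the pooled-variance Student t (df n0+n1-2,
#' the default, matching the equal-variance error model the power study
#' assumes) or the Welch-Satterthwaite variant. Direction is group 1 minus
#' group 0, the same convention as the homologous D-hat.
#'
#' When both groups are constant, `stats::t.test()` refuses; the degenerate
#' case is resolved explicitly: equal constants give t = 0, p = 1, unequal
#' constants give an infinite statistic and p = 0.
#'
#' @param y0,y1 numeric vectors of volumes for group 0 and group 1 (each of
#'   length >= 2).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (`"two-sided"` accepted as an alias).
#' @return A list of class `ttest_result` with `mean0`, `mean1`, `diff`,
#'   `se`, `t_stat`, `df`, `p_value`, `variant`, `alternative`.
#' @export
two_sample_t <- function(y0, y1, variant = c("pooled", "welch"),
                         alternative = c("two.sided", "greater", "less")) {
  variant <- match.arg(variant)
  if (identical(alternative, "two-sided")) alternative <- "two.sided"
  alternative <- match.arg(alternative)
  n0 <- length(y0)
  n1 <- length(y1)
  if (n0 < 2L || n1 < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  m0 <- mean(y0)
  m1 <- mean(y1)
  v0 <- stats::var(y0)
  v1 <- stats::var(y1)
  if (v0 + v1 == 0) {
    diff <- m1 - m0
    t_stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- switch(alternative,
                two.sided = as.numeric(diff == 0),
                greater = if (diff > 0) 0 else 1,
                less = if (diff < 0) 0 else 1)
    return(structure(list(mean0 = m0, mean1 = m1, diff = diff, se = 0,
                          t_stat = t_stat,
                          df = if (variant == "pooled") n0 + n1 - 2 else NA_real_,
                          p_value = p, variant = variant,
                          alternative = alternative),
                     class = "ttest_result"))
  }
  tt <- stats::t.test(y1, y0, var.equal = (variant == "pooled"),
                      alternative = alternative)
  structure(list(
    mean0 = m0, mean1 = m1, diff = m1 - m0,
    se = unname(tt$stderr), t_stat = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value,
    variant = variant, alternative = alternative
  ), class = "ttest_result")
}

#' Pearson product-moment correlation
#'
#' Standard correlation with an explicit degenerate rule: returns `NA` when
#' either vector has zero variance rather than erroring, since scan tables
#' must carry on past constant early time points.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\], or `NA_real_` if undefined.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (length(a) < 2L) {
    stop("need at least 2 observations", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s)\n", x$variant))
  cat(sprintf("  mean1 - mean0 = %.6g,  SE = %.6g\n", x$diff, x$se))
  cat(sprintf("  t = %.4f on %s df,  p = %.4g (%s)\n",
              x$t_stat, format(x$df), x$p_value, x$alternative))
  invisible(x)
}
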