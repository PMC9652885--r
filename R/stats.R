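# Demographic and accuracy-comparison statistics.

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' @param table 2x2 matrix of nonnegative integer counts with no empty
#'   margin.
#' @return List with `statistic` (df = 1) and `p`.
#' @examples
#' chi_square_2x2(matrix(c(7, 14, 6, 15), 2, byrow = TRUE))$p  # 0.7385
#' @export
chi_square_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margin")
  n <- sum(table)
  e <- outer(rowSums(table), colSums(table)) / n
  stat <- sum((table - e)^2 / e)
  list(statistic = stat, df = 1, p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Two-tailed pooled-variance Student's t-test
#'
#' Accepts raw vectors or `(mean, sd, n)` summaries for either group;
#' degrees of freedom `n1 + n2 - 2`.
#'
#' @param a,b Numeric vectors, or lists/vectors `c(mean =, sd =, n =)`.
#' @return List with `t`, `df`, `p`.
#' @examples
#' students_t_two_tailed(c(mean = 74.71, sd = 6.50, n = 21),
#'                       c(mean = 73.71, sd = 4.63, n = 21))$p  # ~0.569
#' @export
students_t_two_tailed <- function(a, b) {
  summarize <- function(v) {
    if (!is.null(names(v)) && all(c("mean", "sd", "n") %in% names(v)))
      list(m = unname(v[["mean"]]), s = unname(v[["sd"]]),
           n = unname(v[["n"]]))
    else list(m = mean(v), s = sd(v), n = length(v))
  }
  sa <- summarize(a); sb <- summarize(b)
  if (sa$n < 2 || sb$n < 2) stop("each group needs n >= 2")
  df <- sa$n + sb$n - 2
  sp2 <- ((sa$n - 1) * sa$s^2 + (sb$n - 1) * sb$s^2) / df
  if (sp2 == 0) stop("zero pooled variance")
  t <- (sa$m - sb$m) / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Standardizes the sample and tests it against N(0, 1); used only as a
#' gate between the t-test and the Wilcoxon test.
#'
#' @param x Numeric vector, n >= 5, non-constant.
#' @return List with `statistic` and `p`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5) stop("n >= 5 required")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("constant input")
  z <- (x - mean(x)) / s
  kt <- suppressWarnings(ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Bonferroni-corrected Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on paired per-fold accuracies (zero
#' differences dropped), with the p-value multiplied by the family size `m`
#' and capped at 1.  Stars follow the corrected-p thresholds
#' 0.05 / 0.001 / 0.0001.
#'
#' @param acc_a,acc_b Equal-length paired accuracy vectors (e.g. 441
#'   per-fold accuracies of two montages).
#' @param m Bonferroni family size.
#' @return A `comparison_report`: list with `test`, `statistic`, `p_raw`,
#'   `p_corrected`, `m`, `stars`, `note`.
#' @export
wilcoxon_bonferroni <- function(acc_a, acc_b, m = 1) {
  stopifnot(length(acc_a) == length(acc_b), m >= 1)
  d <- acc_a - acc_b
  if (all(d == 0)) {
    rep <- list(test = "Wilcoxon signed-rank", statistic = NA_real_,
                p_raw = 1, p_corrected = 1, m = m, stars = "",
                note = "no difference (all paired differences zero)")
    class(rep) <- "comparison_report"
    return(rep)
  }
  wt <- suppressWarnings(wilcox.test(acc_a, acc_b, paired = TRUE,
                                     exact = FALSE, correct = FALSE))
  p_raw <- wt$p.value
  p_corr <- min(1, m * p_raw)
  rep <- list(test = "Wilcoxon signed-rank", statistic = unname(wt$statistic),
              p_raw = p_raw, p_corrected = p_corr, m = m,
              stars = significance_stars(p_corr), note = NULL)
  class(rep) <- "comparison_report"
  rep
}

significance_stars <- function(p) {
  if (p < 1e-4) "***" else if (p < 1e-3) "**" else if (p < 0.05) "*" else ""
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s: p = %.4g (Bonferroni m = %d -> %.4g) %s\n",
              x$test, x$p_raw, x$m, x$p_corrected, x$stars))
  if (!is.null(x$note)) cat("  ", x$note, "\n")
  invisible(x)
}
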