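#' Two-sided Fisher's exact test on a 2x2 product-class table
#'
#' Exact test for association in a 2x2 table of counts, rows being
#' conditions (e.g. wild type vs mutant) and columns outcome classes (e.g.
#' aberrant vs normal-sized BIR product). With the margins fixed, the
#' two-sided p-value sums the hypergeometric probabilities of every table
#' whose point probability does not exceed that of the observed one — the
#' convention of `stats::fisher.test()`, which this wraps.
#'
#' @param a,b,c,d the four cell counts, row-wise: condition 1 gives `a`
#'   events out of `a + b`, condition 2 gives `c` out of `c + d`.
#'   Alternatively pass a 2x2 matrix as `a`.
#' @return the `htest` object; its `p.value` is the two-sided p.
#' @examples
#' fisher_exact(15, 55, 2, 87)$p.value   # aberrant products, 15/70 vs 2/89
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, b, c, d), 2L, byrow = TRUE)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0))
    stop("degenerate table: a condition (row) has no observations")
  # an empty outcome column is a single possible outcome class: p = 1
  stats::fisher.test(tab, alternative = "two.sided")
}

#' Two-sample t test on replicate efficiencies
#'
#' Two-sided comparison of mean efficiency between two groups of replicate
#' experiments. Welch's unequal-variance form is the default (the default
#' behaviour of `stats::t.test()`); the pooled-variance Student form is
#' available with `welch = FALSE`.
#'
#' @param x,y numeric vectors of per-experiment efficiencies, each of
#'   length >= 2.
#' @param welch use the Welch unequal-variance statistic (default).
#' @return the `htest` object with `statistic` and `p.value`.
#' @export
efficiency_t_test <- function(x, y, welch = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      stop("degenerate comparison: both groups constant and equal")
    warning("both groups have zero variance with unequal means; p -> 0")
    return(structure(list(
      statistic = c(t = sign(mean(x) - mean(y)) * Inf), p.value = 0,
      estimate = c(`mean of x` = mean(x), `mean of y` = mean(y)),
      alternative = "two.sided",
      method = "Two Sample t-test (zero-variance limit)",
      data.name = "x and y"), class = "htest"))
  }
  stats::t.test(x, y, alternative = "two.sided", var.equal = !welch)
}

#' Pairwise Fisher tests on aberrant-product fractions
#'
#' Builds the 2x2 table (aberrant, total - aberrant) for every pair of
#' labelled conditions and applies [fisher_exact()]. No multiplicity
#' adjustment is made by default, each comparison standing on its own;
#' `adjust` passes any `stats::p.adjust()` method (e.g. `"BH"`).
#'
#' @param counts data frame with columns `label`, `aberrant`, `total`
#'   (`total >= aberrant`).
#' @param adjust p-value adjustment method, `"none"` by default.
#' @return symmetric matrix of two-sided p-values, 1 on the diagonal.
#' @examples
#' compare_aberrant_fractions(data.frame(
#'   label = c("WT-IVR10", "WT-IVR117"), aberrant = c(15, 3),
#'   total = c(70, 97)))
#' @export
compare_aberrant_fractions <- function(counts, adjust = "none") {
  stopifnot(all(c("label", "aberrant", "total") %in% names(counts)),
            all(counts$total >= counts$aberrant))
  n <- nrow(counts)
  p <- matrix(1, n, n, dimnames = list(counts$label, counts$label))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pv <- fisher_exact(counts$aberrant[i], counts$total[i] - counts$aberrant[i],
                       counts$aberrant[j], counts$total[j] - counts$aberrant[j])$p.value
    p[i, j] <- p[j, i] <- pv
  }
  if (adjust != "none") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  p
}
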