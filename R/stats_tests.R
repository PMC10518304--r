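# Elementary tests of the group-comparison battery: pooled two-sample t
# (from raw samples or printed summaries), 2x2 chi-square, Pearson
# correlation with explicit zero-variance handling, and BH-FDR adjustment.

ttest_result <- function(t, df, p, mean_diff, se) {
  structure(list(t = t, df = df, p = p, mean_diff = mean_diff, se = se),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g (mean diff %.3f, se %.3f)\n",
              x$df, x$t, x$p, x$mean_diff, x$se))
  invisible(x)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Classic equal-variance (Student) test computed from group means, sds and
#' sizes: `t = (m1 - m2) / sqrt(s_p^2 (1/n1 + 1/n2))` with
#' `df = n1 + n2 - 2`. This is the df convention behind published group
#' comparisons of the form t(38) at n = 20 per group.
#'
#' @param m1,sd1,n1,m2,sd2,n2 group means, standard deviations, sizes.
#' @return a `ttest_result`.
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stop_if_not(n1 >= 2 && n2 >= 2, "each group needs n >= 2")
  stop_if_not(sd1 >= 0 && sd2 >= 0, "sds must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  if (se == 0) {
    if (diff == 0) return(ttest_result(0, df, 1, 0, 0))
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  t <- diff / se
  ttest_result(t, df, 2 * pt(-abs(t), df), diff, se)
}

#' Independent-samples t-test
#'
#' Pooled-variance (Student) test by default, matching
#' [ttest_from_summary()] applied to the sample summaries exactly;
#' `pooled = FALSE` gives the Welch variant.
#'
#' @param x,y numeric samples (NAs dropped).
#' @param pooled assume equal variances.
#' @return a `ttest_result`.
#' @export
ttest_independent <- function(x, y, pooled = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stop_if_not(length(x) >= 2 && length(y) >= 2, "each sample needs n >= 2")
  if (pooled) {
    return(ttest_from_summary(mean(x), sd(x), length(x),
                              mean(y), sd(y), length(y)))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  ttest_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
               unname(diff(rev(tt$estimate))), unname(tt$stderr))
}

#' Paired t-test wrapper
#'
#' @param x,y paired samples.
#' @return a `ttest_result`.
#' @export
ttest_paired <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d)]
  stop_if_not(length(d) >= 2, "need >= 2 complete pairs")
  if (sd(d) == 0) {
    if (mean(d) == 0) return(ttest_result(0, length(d) - 1, 1, 0, 0))
    stop("zero variance of paired differences with nonzero mean", call. = FALSE)
  }
  tt <- t.test(d)
  ttest_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
               mean(d), unname(tt$stderr))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table) {
  stop_if_not(is.matrix(table) && all(dim(table) == 2), "need a 2x2 matrix")
  stop_if_not(all(table >= 0) && all(table == round(table)),
              "counts must be non-negative integers")
  stop_if_not(all(rowSums(table) > 0) && all(colSums(table) > 0),
              "table has a zero margin")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' Pearson correlation with zero-variance handling
#'
#' Pairwise-complete product-moment correlation; `p` from
#' `t = r sqrt((n - 2) / (1 - r^2))`. When either variable has zero
#' variance (or fewer than 3 complete pairs remain) an undefined-result
#' record is returned instead of an error, mirroring score columns where
#' every subject attains the ceiling.
#'
#' @param x,y numeric vectors.
#' @return list with `r`, `p`, `n`, `undefined`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, undefined = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `p_adj(i) = min_{j >= i} p_(j) m / j`, capped at 1,
#' returned in the input order. `NA` entries (undefined tests) are excluded
#' from the family and returned as `NA`.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]` (NAs allowed).
#' @param q significance criterion on the adjusted values.
#' @return list with `adjusted` and logical `significant` (NA-safe).
#' @export
bh_fdr_adjust <- function(pvalues, q = 0.05) {
  stop_if_not(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)),
              "p-values must lie in [0, 1]")
  adjusted <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  adjusted[ok] <- p.adjust(pvalues[ok], method = "BH")
  list(adjusted = adjusted,
       significant = !is.na(adjusted) & adjusted <= q)
}
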