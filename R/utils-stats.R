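# Shared test machinery: Mann-Whitney and 2x2 Fisher wrappers used by the
# burden, allele-ratio and event-type-distribution comparisons.

# Two-sided Mann-Whitney U. Exact distribution when both groups have <= 8
# observations and no ties; otherwise the normal approximation with
# continuity and tie correction. Degenerate input (no variation across the
# pooled samples) yields p = 1 by convention.
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) {
    abort("both groups must contain at least one non-missing value")
  }
  n_x <- length(x)
  n_y <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(list(
      statistic = n_x * n_y / 2, p_value = 1,
      n_a = n_x, n_b = n_y, method = "degenerate (no variation)"
    ))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- n_x <= 8 && n_y <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    n_a = n_x, n_b = n_y,
    method = if (exact) "exact" else "normal approximation"
  )
}

# Two-sided Fisher exact test on a 2x2 table. Reports both the sample
# cross-product odds ratio and the conditional MLE from fisher.test.
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) abort("`tab` must be a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must contain non-negative integer counts")
  }
  ht <- stats::fisher.test(tab)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (!is.finite(or_sample)) or_sample <- NA_real_
  list(
    p_value = ht$p.value,
    odds_ratio = or_sample,
    odds_ratio_mle = unname(ht$estimate)
  )
}
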