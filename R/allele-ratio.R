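#' Mutant-allele mRNA fraction from base counts
#'
#' Fraction of reads carrying the mutant base among all four bases at the
#' mutation locus, per sample. Samples below `min_depth` are marked
#' unevaluable (fraction NA).
#'
#' @param counts Tibble with `sample_id` and integer columns `A`, `C`, `G`,
#'   `T` (e.g. from [simulate_pileup()] or a pileup export).
#' @param mutant_base Single base among A/C/G/T.
#' @param min_depth Minimum locus depth (default 20).
#' @return A tibble: `sample_id`, `depth`, `fraction`, `evaluable`.
#' @examples
#' counts <- tibble::tibble(sample_id = "s1", A = 6L, C = 0L, G = 4L, T = 0L)
#' allele_fraction(counts, mutant_base = "A", min_depth = 5)
#' @export
allele_fraction <- function(counts, mutant_base = "A", min_depth = 20) {
  assert_columns(counts, c("sample_id", "A", "C", "G", "T"), "counts")
  if (!mutant_base %in% c("A", "C", "G", "T")) {
    abort("`mutant_base` must be one of A, C, G, T")
  }
  base_mat <- as.matrix(counts[c("A", "C", "G", "T")])
  if (any(base_mat < 0, na.rm = TRUE)) abort("base counts must be non-negative")
  depth <- rowSums(base_mat)
  evaluable <- !is.na(depth) & depth >= min_depth & depth > 0
  tibble(
    sample_id = counts$sample_id,
    depth = depth,
    fraction = ifelse(evaluable, base_mat[, mutant_base] / depth, NA_real_),
    evaluable = evaluable
  )
}

#' Classify mutant mRNA ratios into quasi-WT and typical bands
#'
#' Three-band classification of the mutant:wild-type mRNA ratio. The
#' defaults encode the published bands: quasi-WT tumors show ratios of
#' 0.27-0.31 despite carrying the mutation (so any fraction at or below
#' 0.31 is labelled `quasi_wt`), while typical mutant samples show 0.43 or
#' above (`typical_s34f`); fractions between the bands are `indeterminate`.
#' Both bounds are inclusive. The classification is monotone in the
#' fraction.
#'
#' @param fractions A tibble with a `fraction` column (e.g. from
#'   [allele_fraction()]) or a bare numeric vector.
#' @param quasi_max Upper edge of the quasi-WT band (default 0.31).
#' @param typical_min Lower edge of the typical band (default 0.43).
#' @return The input with a `label` factor column
#'   (`quasi_wt` < `indeterminate` < `typical_s34f`); NA fractions get NA
#'   labels.
#' @examples
#' classify_ratio(c(0.29, 0.37, 0.43))
#' @export
classify_ratio <- function(fractions, quasi_max = 0.31, typical_min = 0.43) {
  if (!is_scalar_number(quasi_max) || !is_scalar_number(typical_min) ||
      quasi_max >= typical_min) {
    abort("`quasi_max` must be smaller than `typical_min`")
  }
  if (is.numeric(fractions)) {
    fractions <- tibble(fraction = fractions)
  }
  assert_columns(fractions, "fraction", "fractions")
  f <- fractions$fraction
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    abort("fractions must lie in [0, 1]")
  }
  lab <- rep(NA_character_, length(f))
  lab[!is.na(f) & f <= quasi_max] <- "quasi_wt"
  lab[!is.na(f) & f >= typical_min] <- "typical_s34f"
  lab[!is.na(f) & is.na(lab)] <- "indeterminate"
  out <- as_tibble(fractions)
  out$label <- factor(lab, levels = c("quasi_wt", "indeterminate",
                                      "typical_s34f"))
  out
}

#' Co-occurrence of ratio class and a driver mutation
#'
#' Builds the 2 x 2 table of ratio class (quasi-WT vs typical) against
#' driver-mutation status, with the sample cross-product odds ratio, the
#' conditional maximum-likelihood odds ratio, and a two-sided Fisher exact
#' p. Indeterminate and unlabelled samples are excluded. When either class
#' has no samples the p-value is undefined and reported as NA.
#'
#' @param classes Either a tibble with `label` (from [classify_ratio()])
#'   and a logical driver column, or a ready-made 2 x 2 matrix (rows:
#'   quasi-WT, typical; columns: driver, no driver).
#' @param driver_col Name of the logical driver column (default
#'   `"driver"`).
#' @return A list of class `cooccurrence`: `table`, `odds_ratio`,
#'   `odds_ratio_mle`, `p_value`, `n_excluded`.
#' @examples
#' cooccurrence_table(matrix(c(3, 5, 1, 4), nrow = 2))
#' @export
cooccurrence_table <- function(classes, driver_col = "driver") {
  n_excluded <- 0L
  if (is.matrix(classes)) {
    tab <- classes
    if (!all(dim(tab) == c(2L, 2L))) abort("matrix input must be 2 x 2")
    dimnames(tab) <- list(class = c("quasi_wt", "typical_s34f"),
                          driver = c("driver", "no_driver"))
  } else {
    assert_columns(classes, c("label", driver_col), "classes")
    keep <- classes$label %in% c("quasi_wt", "typical_s34f") &
      !is.na(classes[[driver_col]])
    n_excluded <- sum(!keep)
    kept <- classes[keep, ]
    tab <- matrix(
      c(
        sum(kept$label == "quasi_wt" & kept[[driver_col]]),
        sum(kept$label == "typical_s34f" & kept[[driver_col]]),
        sum(kept$label == "quasi_wt" & !kept[[driver_col]]),
        sum(kept$label == "typical_s34f" & !kept[[driver_col]])
      ),
      nrow = 2,
      dimnames = list(class = c("quasi_wt", "typical_s34f"),
                      driver = c("driver", "no_driver"))
    )
  }
  if (any(rowSums(tab) == 0)) {
    ft <- list(p_value = NA_real_, odds_ratio = NA_real_,
               odds_ratio_mle = NA_real_)
  } else {
    ft <- fisher_exact_2x2(tab)
  }
  structure(
    list(table = tab, odds_ratio = ft$odds_ratio,
         odds_ratio_mle = ft$odds_ratio_mle, p_value = ft$p_value,
         n_excluded = n_excluded),
    class = "cooccurrence"
  )
}

#' @export
print.cooccurrence <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio %.3g (conditional MLE %.3g), Fisher p = %.4g\n",
              x$odds_ratio, x$odds_ratio_mle, x$p_value))
  invisible(x)
}

#' @export
tidy.cooccurrence <- function(x, ...) {
  as_tibble(as.data.frame(x$table, responseName = "n"))
}

#' @export
glance.cooccurrence <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, odds_ratio_mle = x$odds_ratio_mle,
         p_value = x$p_value, n_excluded = x$n_excluded)
}

#' Compare mutant mRNA fractions between two groups
#'
#' Two-sided Mann-Whitney U test on per-sample mutant fractions (same test
#' machinery as [compare_burden()]).
#'
#' @param fractions Tibble with `fraction` and a grouping column.
#' @param group_a,group_b Group labels.
#' @param group_col Name of the grouping column (default `"group"`).
#' @return One-row tibble: groups, sizes, U statistic, `p_value`, `method`.
#' @export
compare_fractions <- function(fractions, group_a, group_b,
                              group_col = "group") {
  assert_columns(fractions, c("fraction", group_col), "fractions")
  x <- fractions$fraction[fractions[[group_col]] %in% group_a]
  y <- fractions$fraction[fractions[[group_col]] %in% group_b]
  if (sum(!is.na(x)) < 3 || sum(!is.na(y)) < 3) {
    abort("each group needs at least 3 non-missing fractions")
  }
  mw <- mann_whitney(x, y)
  tibble(
    group_a = group_a, group_b = group_b, n_a = mw$n_a, n_b = mw$n_b,
    statistic = mw$statistic, p_value = mw$p_value, method = mw$method
  )
}
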