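#' Per-event robust PSI statistics
#'
#' Median and interquartile range of PSI over non-missing samples, the
#' reference distribution for the outlier-burden rule. Quartiles are
#' linearly interpolated order statistics (R quantile type 7) by default.
#' Events with fewer than four non-missing values are excluded with a
#' warning. Input should already be restricted with
#' `filter_events(x, burden_rules())`.
#'
#' @param psi Long PSI tibble (`event_id`, `sample_id`, `psi`).
#' @param quartile_type Quantile algorithm passed to [stats::quantile()].
#' @return A tibble: `event_id`, `median`, `iqr`, `n_used`.
#' @examples
#' psi <- tibble::tibble(
#'   event_id = "e1", sample_id = paste0("s", 1:4),
#'   psi = c(10, 20, 30, 40)
#' )
#' event_robust_stats(psi) # median 25, IQR 17.5
#' @export
event_robust_stats <- function(psi, quartile_type = 7) {
  assert_columns(psi, c("event_id", "sample_id", "psi"), "psi")
  out <- psi |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      n_used = sum(!is.na(.data$psi)),
      median = stats::median(.data$psi, na.rm = TRUE),
      iqr = if (sum(!is.na(.data$psi)) == 0) NA_real_ else {
        q <- stats::quantile(.data$psi, c(0.25, 0.75), na.rm = TRUE,
                             type = quartile_type, names = FALSE)
        q[2] - q[1]
      },
      .groups = "drop"
    ) |>
    dplyr::relocate("event_id", "median", "iqr", "n_used")
  few <- out$n_used < 4
  if (any(few)) {
    warn(sprintf("%d event(s) excluded: fewer than 4 non-missing values",
                 sum(few)))
    out <- out[!few, ]
  }
  out
}

#' Flag outlying PSI cells
#'
#' A cell is flagged altered when its PSI deviates from the event median by
#' more than `k` times the event IQR *and* by more than `min_dev` PSI
#' points. Deviation is absolute (two-sided), so both excess inclusion and
#' excess exclusion count. Missing cells are never flagged. With IQR = 0
#' the rule reduces exactly to `|PSI - median| > min_dev`.
#'
#' @param psi Long PSI tibble covering the same cohort the statistics were
#'   computed on.
#' @param stats Output of [event_robust_stats()]; must not contain events
#'   absent from `psi`. Events of `psi` without statistics (excluded
#'   upstream) are ignored.
#' @param k IQR multiplier (default 1.5).
#' @param min_dev Minimum absolute deviation in PSI points (default 10).
#' @return A tibble: `event_id`, `sample_id`, `psi`, `altered`.
#' @export
flag_alterations <- function(psi, stats, k = 1.5, min_dev = 10) {
  assert_columns(psi, c("event_id", "sample_id", "psi"), "psi")
  assert_columns(stats, c("event_id", "median", "iqr"), "stats")
  if (!is_scalar_number(k) || k < 0) abort("`k` must be non-negative")
  if (!is_scalar_number(min_dev) || min_dev < 0) {
    abort("`min_dev` must be non-negative")
  }
  orphan <- setdiff(stats$event_id, psi$event_id)
  if (length(orphan) > 0) {
    abort(sprintf("stats contain %d event(s) absent from `psi`",
                  length(orphan)))
  }
  out <- dplyr::inner_join(
    psi[c("event_id", "sample_id", "psi")],
    stats[c("event_id", "median", "iqr")],
    by = "event_id"
  )
  dev <- abs(out$psi - out$median)
  out$altered <- !is.na(out$psi) & dev > k * out$iqr & dev > min_dev
  out[c("event_id", "sample_id", "psi", "altered")]
}

#' Per-sample splicing-alteration burden
#'
#' @param flags Output of [flag_alterations()].
#' @return A tibble of class `burden_profile`: `sample_id`, `burden`
#'   (number of altered events), `n_events_evaluated`.
#' @export
sample_burden <- function(flags) {
  assert_columns(flags, c("event_id", "sample_id", "altered"), "flags")
  out <- flags |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      burden = sum(.data$altered, na.rm = TRUE),
      n_events_evaluated = dplyr::n_distinct(.data$event_id),
      .groups = "drop"
    )
  structure(out, class = c("burden_profile", class(out)))
}

#' Compare alteration burden between two sample groups
#'
#' Two-sided Mann-Whitney U test on per-sample burdens; exact when both
#' groups have at most eight samples and no ties, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param profiles A [sample_burden()] result.
#' @param meta Sample metadata with `sample_id` and `group`.
#' @param group_a,group_b Group labels; at least three samples each.
#' @return One-row tibble: groups, sample sizes, U statistic, `p_value`,
#'   `method`.
#' @export
compare_burden <- function(profiles, meta, group_a, group_b) {
  assert_columns(profiles, c("sample_id", "burden"), "profiles")
  assert_columns(meta, c("sample_id", "group"), "meta")
  joined <- dplyr::inner_join(profiles, meta, by = "sample_id")
  x <- joined$burden[joined$group %in% group_a]
  y <- joined$burden[joined$group %in% group_b]
  if (length(x) < 3 || length(y) < 3) {
    abort("each group needs at least 3 samples with burden values")
  }
  mw <- mann_whitney(x, y)
  tibble(
    group_a = group_a, group_b = group_b,
    n_a = mw$n_a, n_b = mw$n_b,
    statistic = mw$statistic, p_value = mw$p_value, method = mw$method
  )
}
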