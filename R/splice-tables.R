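#' Compute percent spliced in from inclusion/exclusion counts
#'
#' PSI = 100 * inclusion / (inclusion + exclusion) per event and sample.
#' Cells whose total count falls below `min_total`, or whose counts are
#' missing, become missing PSI. The default floor of 10 normalized counts
#' guards against degenerate PSI estimates from near-zero coverage.
#'
#' @param counts Long tibble with columns `event_id`, `sample_id`,
#'   `inclusion`, `exclusion`; event annotation columns are carried through.
#' @param min_total Non-negative minimum total count for a cell to be
#'   evaluated.
#' @return The input tibble with `inclusion`/`exclusion` replaced by `psi`.
#' @examples
#' counts <- tibble::tibble(
#'   event_id = "e1", sample_id = c("s1", "s2"),
#'   inclusion = c(30, 0), exclusion = c(10, 0)
#' )
#' compute_psi(counts, min_total = 10)
#' @export
compute_psi <- function(counts, min_total = 10) {
  assert_columns(counts, c("event_id", "sample_id", "inclusion", "exclusion"),
                 "counts")
  if (!is_scalar_number(min_total) || min_total < 0) {
    abort("`min_total` must be a single non-negative number")
  }
  if (any(counts$inclusion < 0, na.rm = TRUE) ||
      any(counts$exclusion < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  total <- counts$inclusion + counts$exclusion
  psi <- ifelse(!is.na(total) & total >= min_total & total > 0,
                100 * counts$inclusion / total, NA_real_)
  out <- dplyr::select(counts, -"inclusion", -"exclusion")
  out$psi <- psi
  as_tibble(out)
}

#' Event exclusion rules
#'
#' Constructor for the rule set consumed by [filter_events()], plus the two
#' presets used by the pipeline: [diff_splicing_rules()] drops junction-only
#' alternative 5'/3' splice-site events and novel intron-retention events
#' (the differential-splicing filters); [burden_rules()] additionally drops
#' every junction-only event and any event missing in more than 25% of
#' samples (the outlier-burden filters).
#'
#' @param drop_jcn_only_alt_ss Drop junction-only alternative 5'/3'
#'   splice-site events.
#' @param drop_jcn_only Drop all junction-only events.
#' @param drop_novel_ir Drop intron-retention events flagged novel.
#' @param max_missing_frac Drop events with a missing fraction strictly
#'   greater than this threshold (NULL = rule off). Missingness is computed
#'   over all samples of the analysis cohort.
#' @return A list of class `filter_rules`.
#' @export
filter_rules <- function(drop_jcn_only_alt_ss = FALSE,
                         drop_jcn_only = FALSE,
                         drop_novel_ir = FALSE,
                         max_missing_frac = NULL) {
  if (!is.null(max_missing_frac)) {
    assert_fraction(max_missing_frac, "max_missing_frac")
  }
  structure(
    list(
      drop_jcn_only_alt_ss = isTRUE(drop_jcn_only_alt_ss),
      drop_jcn_only = isTRUE(drop_jcn_only),
      drop_novel_ir = isTRUE(drop_novel_ir),
      max_missing_frac = max_missing_frac
    ),
    class = "filter_rules"
  )
}

#' @rdname filter_rules
#' @export
diff_splicing_rules <- function() {
  filter_rules(drop_jcn_only_alt_ss = TRUE, drop_novel_ir = TRUE)
}

#' @rdname filter_rules
#' @export
burden_rules <- function() {
  filter_rules(drop_jcn_only = TRUE, drop_novel_ir = TRUE,
               max_missing_frac = 0.25)
}

#' Apply event-level exclusion rules
#'
#' Drops events according to a [filter_rules()] rule set, preserving input
#' order. Works on a long per-cell table (event annotations plus
#' `sample_id` and `psi` or `inclusion` columns, from which missingness is
#' derived) or on an event-level annotation table (missingness rule then
#' requires per-cell data and is skipped with a warning).
#'
#' @param x Tibble with at least `event_id`, `event_type`, `novelty`,
#'   `junction_only`.
#' @param rules A [filter_rules()] object; `filter_rules()` (all off) is the
#'   identity.
#' @return The surviving subset of `x`, with attribute `removed`: a tibble
#'   of events removed per rule.
#' @examples
#' ev <- tibble::tibble(
#'   event_id = c("e1", "e2", "e3", "e4"),
#'   event_type = c("cassette", "alt_3ss", "intron_retention",
#'                  "intron_retention"),
#'   novelty = c("known", "known", "novel", "known"),
#'   junction_only = c(FALSE, TRUE, FALSE, FALSE)
#' )
#' filter_events(ev, diff_splicing_rules())
#' @export
filter_events <- function(x, rules = filter_rules()) {
  assert_columns(x, c("event_id", "event_type", "novelty", "junction_only"), "x")
  if (!inherits(rules, "filter_rules")) abort("`rules` must come from filter_rules()")
  ev <- dplyr::distinct(
    dplyr::select(x, "event_id", "event_type", "novelty", "junction_only")
  )
  keep <- rep(TRUE, nrow(ev))
  removed <- list()
  drop_by <- function(keep, cond, rule) {
    newly <- keep & cond
    removed[[rule]] <<- tibble(rule = rule, n_removed = sum(newly))
    keep & !cond
  }
  if (rules$drop_jcn_only_alt_ss) {
    keep <- drop_by(
      keep, ev$junction_only & ev$event_type %in% c("alt_5ss", "alt_3ss"),
      "junction_only_alt_ss"
    )
  }
  if (rules$drop_jcn_only) {
    keep <- drop_by(keep, ev$junction_only, "junction_only")
  }
  if (rules$drop_novel_ir) {
    keep <- drop_by(
      keep, ev$event_type == "intron_retention" & ev$novelty == "novel",
      "novel_intron_retention"
    )
  }
  if (!is.null(rules$max_missing_frac)) {
    value_col <- intersect(c("psi", "inclusion"), names(x))[1]
    if ("sample_id" %in% names(x) && !is.na(value_col)) {
      miss <- dplyr::summarise(
        dplyr::group_by(x, .data$event_id),
        missing_frac = mean(is.na(.data[[value_col]])), .groups = "drop"
      )
      mf <- miss$missing_frac[match(ev$event_id, miss$event_id)]
      keep <- drop_by(keep, mf > rules$max_missing_frac, "missingness")
    } else {
      warn("missingness rule skipped: `x` carries no per-sample values")
    }
  }
  out <- dplyr::filter(x, .data$event_id %in% ev$event_id[keep])
  attr(out, "removed") <- if (length(removed) > 0) {
    dplyr::bind_rows(removed)
  } else {
    tibble(rule = character(0), n_removed = integer(0))
  }
  out
}

juncbase_core_cols <- c("event_id", "event_type", "gene", "novelty",
                        "junction_only", "redundancy_group")
count_pair_re <- "^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?;-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$"

#' Read and write splicing count tables
#'
#' The on-disk dialect is a tab-separated table with one row per event:
#' leading annotation columns (`event_id`, `event_type`, `gene`, `novelty`,
#' `junction_only`, `redundancy_group`), then one column per sample holding
#' `"inclusion;exclusion"` count pairs, with `NA` for missing cells.
#' Unrecognized non-count columns are preserved as extra event annotations.
#' Reading and writing round-trip losslessly.
#'
#' @param path File path.
#' @return `read_juncbase_table()` returns the long counts tibble used by
#'   [compute_psi()].
#' @export
read_juncbase_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = "NA", progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed table: parsing problem at row %d, column %d",
                  probs$row[1], probs$col[1]))
  }
  assert_columns(raw, juncbase_core_cols, "table")
  dup <- raw$event_id[duplicated(raw$event_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated event id(s): %s",
                  paste(head(unique(dup), 3), collapse = ", ")))
  }
  other <- setdiff(names(raw), juncbase_core_cols)
  is_sample <- vapply(other, function(cl) {
    v <- raw[[cl]][!is.na(raw[[cl]])]
    length(v) > 0 && all(grepl(count_pair_re, v))
  }, logical(1))
  sample_cols <- other[is_sample]
  extra_cols <- other[!is_sample]
  if (length(sample_cols) == 0) abort("no sample count columns found")

  ann <- raw[c(juncbase_core_cols, extra_cols)]
  ann$junction_only <- toupper(ann$junction_only) == "TRUE"
  long <- tidyr::pivot_longer(
    raw[c("event_id", sample_cols)], -"event_id",
    names_to = "sample_id", values_to = "pair"
  )
  parts <- strsplit(long$pair, ";", fixed = TRUE)
  incl <- suppressWarnings(as.numeric(vapply(
    parts, function(p) if (length(p) == 2) p[1] else NA_character_,
    character(1)
  )))
  excl <- suppressWarnings(as.numeric(vapply(
    parts, function(p) if (length(p) == 2) p[2] else NA_character_,
    character(1)
  )))
  bad <- !is.na(long$pair) & (is.na(incl) | is.na(excl))
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("non-numeric count pair for event %s, sample %s",
                  long$event_id[i], long$sample_id[i]))
  }
  if (any(incl < 0, na.rm = TRUE) || any(excl < 0, na.rm = TRUE)) {
    abort("negative counts are not allowed")
  }
  long$inclusion <- incl
  long$exclusion <- excl
  long$pair <- NULL
  dplyr::left_join(long, ann, by = "event_id") |>
    dplyr::relocate(dplyr::all_of(juncbase_core_cols)) |>
    dplyr::relocate("inclusion", "exclusion", .after = dplyr::last_col())
}

#' @rdname read_juncbase_table
#' @param counts Long counts tibble (as produced by
#'   [simulate_splicing_cohort()] or [read_juncbase_table()]).
#' @export
write_juncbase_table <- function(counts, path) {
  assert_columns(counts, c(juncbase_core_cols, "sample_id", "inclusion",
                           "exclusion"), "counts")
  pair <- ifelse(
    is.na(counts$inclusion) | is.na(counts$exclusion), NA_character_,
    paste0(sprintf("%.15g", counts$inclusion), ";",
           sprintf("%.15g", counts$exclusion))
  )
  extra_cols <- setdiff(names(counts),
                        c(juncbase_core_cols, "sample_id", "inclusion",
                          "exclusion"))
  tab <- counts[c("event_id", "sample_id")]
  tab$pair <- pair
  wide <- tidyr::pivot_wider(tab, names_from = "sample_id",
                             values_from = "pair")
  ann <- dplyr::distinct(
    counts[c(juncbase_core_cols, extra_cols)]
  )
  out <- dplyr::left_join(ann, wide, by = "event_id")
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read and write PSI matrices
#'
#' Wide TSV with `event_id` plus optional annotation columns, then one
#' numeric PSI column per sample; `NA` marks missing cells.
#'
#' @param psi Long PSI tibble from [compute_psi()].
#' @param path File path.
#' @export
write_psi_matrix <- function(psi, path) {
  assert_columns(psi, c("event_id", "sample_id", "psi"), "psi")
  ann_cols <- intersect(juncbase_core_cols, names(psi))
  wide <- tidyr::pivot_wider(psi[c("event_id", "sample_id", "psi")],
                             names_from = "sample_id", values_from = "psi")
  ann <- dplyr::distinct(psi[ann_cols])
  out <- dplyr::left_join(ann, wide, by = "event_id")
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_psi_matrix
#' @export
read_psi_matrix <- function(path) {
  raw <- readr::read_tsv(path, na = "NA", progress = FALSE,
                         show_col_types = FALSE)
  assert_columns(raw, "event_id", "table")
  ann_cols <- intersect(juncbase_core_cols, names(raw))
  sample_cols <- setdiff(names(raw), ann_cols)
  long <- tidyr::pivot_longer(raw, dplyr::all_of(sample_cols),
                              names_to = "sample_id", values_to = "psi")
  bad <- !is.na(long$psi) & (long$psi < 0 | long$psi > 100)
  if (any(bad)) abort("PSI values must lie in [0, 100]")
  long
}
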