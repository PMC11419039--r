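#' Two-group differential splicing
#'
#' Per event, compares mean PSI between a reference and a test group with a
#' two-sample t-test (pooled-variance by default, Welch by flag), applies
#' Benjamini-Hochberg correction across all tested events of the
#' comparison, and calls an event significant when the adjusted p falls
#' below `padj_max` and |dPSI| reaches `dpsi_min` (defaults 0.25 and 10).
#' Events with fewer than two non-missing PSI values in either group are
#' reported untested and excluded from the correction family.
#'
#' Degenerate events where both groups are constant yield p = 1 when the
#' constants agree and the smallest positive double when they differ, so
#' zero-variance ties never propagate NaN.
#'
#' @param psi Long PSI tibble (`event_id`, `sample_id`, `psi`, plus optional
#'   `gene`/`event_type` annotations carried into the result).
#' @param meta Sample metadata with `sample_id` and `group`.
#' @param ref_group,test_group Group labels in `meta$group`; dPSI is
#'   test minus reference.
#' @param test_flavor `"pooled"` (default) or `"welch"`.
#' @param padj_max,dpsi_min Significance thresholds.
#' @return A tibble of class `diff_splicing`, one row per event:
#'   `event_id`, annotations, `mean_psi_ref`, `mean_psi_test`, `delta_psi`,
#'   `p_raw`, `p_adj`, `n_ref`, `n_test`, `tested`, `significant`.
#' @examples
#' sim <- simulate_splicing_cohort(sim_config(seed = 2, n_events = 150))
#' psi <- compute_psi(sim$counts)
#' res <- compare_groups(psi, sim$samples, "ref", "test")
#' glance(res)
#' @export
compare_groups <- function(psi, meta, ref_group, test_group,
                           test_flavor = c("pooled", "welch"),
                           padj_max = 0.25, dpsi_min = 10) {
  test_flavor <- match.arg(test_flavor)
  assert_columns(psi, c("event_id", "sample_id", "psi"), "psi")
  assert_columns(meta, c("sample_id", "group"), "meta")
  for (g in c(ref_group, test_group)) {
    if (!g %in% meta$group) abort(sprintf("unknown group label: %s", g))
  }
  ref_samples <- meta$sample_id[meta$group %in% ref_group]
  test_samples <- meta$sample_id[meta$group %in% test_group]

  wide <- tidyr::pivot_wider(psi[c("event_id", "sample_id", "psi")],
                             names_from = "sample_id", values_from = "psi")
  m <- as.matrix(wide[-1])
  group_stats <- function(mm) {
    n <- rowSums(!is.na(mm))
    mu <- rowMeans(mm, na.rm = TRUE)
    mu[n == 0] <- NA_real_
    ss <- rowSums((mm - mu)^2, na.rm = TRUE)
    v <- ifelse(n > 1, ss / (n - 1), NA_real_)
    list(n = n, mu = mu, v = v)
  }
  a <- group_stats(m[, colnames(m) %in% ref_samples, drop = FALSE])
  b <- group_stats(m[, colnames(m) %in% test_samples, drop = FALSE])
  tested <- a$n >= 2 & b$n >= 2
  if (!any(tested)) warn("no event had two or more non-missing values per group")
  dpsi <- b$mu - a$mu

  if (test_flavor == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se <- sqrt(a$v / a$n + b$v / b$n)
    df <- se^4 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
  }
  p <- 2 * pt(-abs(dpsi / se), df)
  degenerate <- tested & !is.na(se) & se == 0
  p[degenerate] <- ifelse(abs(dpsi[degenerate]) < 1e-12, 1,
                          .Machine$double.xmin)
  p[!tested] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- p.adjust(p[tested], method = "BH")

  out <- tibble(
    event_id = wide$event_id,
    mean_psi_ref = a$mu, mean_psi_test = b$mu, delta_psi = dpsi,
    p_raw = p, p_adj = p_adj, n_ref = a$n, n_test = b$n,
    tested = tested,
    significant = tested & !is.na(p_adj) & p_adj < padj_max &
      abs(dpsi) >= dpsi_min
  )
  ann_cols <- intersect(c("gene", "event_type", "redundancy_group"), names(psi))
  if (length(ann_cols) > 0) {
    ann <- dplyr::distinct(psi[c("event_id", ann_cols)])
    out <- dplyr::left_join(out, ann, by = "event_id") |>
      dplyr::relocate(dplyr::all_of(ann_cols), .after = "event_id")
  }
  structure(
    out,
    class = c("diff_splicing", class(out)),
    ref_group = ref_group, test_group = test_group,
    padj_max = padj_max, dpsi_min = dpsi_min, test_flavor = test_flavor
  )
}

#' @export
tidy.diff_splicing <- function(x, ...) {
  out <- x
  attributes(out)[c("ref_group", "test_group", "padj_max", "dpsi_min",
                    "test_flavor")] <- NULL
  class(out) <- setdiff(class(out), "diff_splicing")
  as_tibble(out)
}

#' @export
glance.diff_splicing <- function(x, ...) {
  tibble(
    n_events = nrow(x),
    n_tested = sum(x$tested),
    n_significant = sum(x$significant, na.rm = TRUE),
    ref_group = attr(x, "ref_group"),
    test_group = attr(x, "test_group"),
    padj_max = attr(x, "padj_max"),
    dpsi_min = attr(x, "dpsi_min"),
    test_flavor = attr(x, "test_flavor")
  )
}

#' Keep one event per redundancy group
#'
#' Splicing pipelines emit overlapping descriptions of the same underlying
#' change; within each redundancy group this keeps the event with the
#' smallest adjusted p, breaking ties by largest |dPSI| and then by
#' lexicographically smallest event id. Events without a redundancy group
#' pass through untouched; input order is preserved.
#'
#' @param results A [compare_groups()] result (or any tibble with
#'   `event_id`, `p_adj`, `delta_psi`).
#' @param events Optional event annotation table supplying
#'   `redundancy_group` when `results` lacks the column.
#' @return The non-redundant subset of `results`.
#' @export
make_nonredundant <- function(results, events = NULL) {
  assert_columns(results, c("event_id", "p_adj", "delta_psi"), "results")
  if (!"redundancy_group" %in% names(results)) {
    if (is.null(events)) {
      abort("`results` has no redundancy_group column; supply `events`")
    }
    assert_columns(events, c("event_id", "redundancy_group"), "events")
    results <- dplyr::left_join(
      results, dplyr::distinct(events[c("event_id", "redundancy_group")]),
      by = "event_id"
    )
  }
  results$.row <- seq_len(nrow(results))
  grouped <- !is.na(results$redundancy_group)
  best <- results[grouped, ] |>
    dplyr::group_by(.data$redundancy_group) |>
    dplyr::arrange(.data$p_adj, dplyr::desc(abs(.data$delta_psi)),
                   .data$event_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  out <- dplyr::bind_rows(results[!grouped, ], best) |>
    dplyr::arrange(.data$.row)
  out$.row <- NULL
  out
}

#' Assign redundancy groups to events from their identifiers
#'
#' Real splicing tables carry no explicit redundancy annotation. As a
#' conservative proxy, events sharing gene and event type are grouped
#' whenever their identifiers share any long numeric (coordinate) token.
#'
#' @param events Tibble with `event_id`, `gene`, `event_type`.
#' @return `events` with a filled `redundancy_group` column (NA for
#'   singleton groups).
#' @export
assign_redundancy_groups <- function(events) {
  assert_columns(events, c("event_id", "gene", "event_type"), "events")
  ev <- dplyr::distinct(events, .data$event_id, .keep_all = TRUE)
  tokens <- lapply(regmatches(ev$event_id,
                              gregexpr("[0-9]{3,}", ev$event_id)), unique)
  key <- paste(ev$gene, ev$event_type)
  parent <- seq_len(nrow(ev))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    seen <- new.env(parent = emptyenv())
    for (i in idx) {
      for (tok in tokens[[i]]) {
        j <- seen[[tok]]
        if (is.null(j)) {
          assign(tok, i, envir = seen)
        } else {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  root <- vapply(seq_len(nrow(ev)), find, integer(1))
  sizes <- table(root)
  grp <- ifelse(sizes[as.character(root)] > 1,
                sprintf("rg%05d", root), NA_character_)
  events$redundancy_group <- grp[match(events$event_id, ev$event_id)]
  events
}

#' Count significant events per splicing category
#'
#' @param results A [compare_groups()] result; rows with `significant ==
#'   TRUE` are counted when the column is present (set
#'   `only_significant = FALSE` to count all rows). Zero-count categories
#'   are reported.
#' @param label Optional comparison label stored on the result.
#' @param only_significant Restrict to significant events (default).
#' @return A tibble of class `event_type_distribution`: `event_type`
#'   (factor over the 8 categories) and `n`.
#' @export
event_type_distribution <- function(results, label = NULL,
                                    only_significant = TRUE) {
  assert_columns(results, "event_type", "results")
  if (only_significant && "significant" %in% names(results)) {
    results <- dplyr::filter(results, .data$significant)
  }
  counts <- table(factor(results$event_type, levels = EVENT_TYPES))
  out <- tibble(
    event_type = factor(EVENT_TYPES, levels = EVENT_TYPES),
    n = as.integer(counts)
  )
  structure(out, class = c("event_type_distribution", class(out)),
            label = label)
}

#' Compare two splicing event-type distributions
#'
#' Overall difference assessed by an exact test on the 2 x 8 contingency
#' table (Monte-Carlo p with a fixed seed and at least 1e5 resamples when
#' exact enumeration is infeasible); per category, a 2 x 2 Fisher exact
#' test of that category against all others, BH-corrected across the eight
#' categories. Categories empty in both distributions are dropped from the
#' overall table.
#'
#' @param a,b [event_type_distribution()] objects over the same categories.
#' @param n_resample Monte-Carlo resamples for the overall test fallback.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return A list of class `event_type_comparison`: `overall_p`, `method`,
#'   and `per_category` (tibble with counts, `p`, `p_adj`, `odds_ratio`).
#' @export
compare_distributions <- function(a, b, n_resample = 1e5, seed = 1L) {
  for (d in list(a, b)) {
    if (!inherits(d, "event_type_distribution")) {
      abort("`a` and `b` must come from event_type_distribution()")
    }
  }
  if (!identical(as.character(a$event_type), as.character(b$event_type))) {
    abort("distributions must cover the same categories in the same order")
  }
  tab <- rbind(a = a$n, b = b$n)
  colnames(tab) <- as.character(a$event_type)
  if (sum(tab) == 0) abort("both distributions are empty")
  nz <- colSums(tab) > 0
  overall_tab <- tab[, nz, drop = FALSE]
  exact <- tryCatch(
    stats::fisher.test(overall_tab, workspace = 2e7),
    error = function(e) NULL
  )
  if (!is.null(exact)) {
    overall_p <- exact$p.value
    method <- "exact"
  } else {
    mc <- with_sub_seed(seed, 0L, {
      stats::fisher.test(overall_tab, simulate.p.value = TRUE,
                         B = as.integer(n_resample))
    })
    overall_p <- mc$p.value
    method <- sprintf("Monte-Carlo (B = %d)", as.integer(n_resample))
  }
  per_category <- purrr::map_dfr(seq_len(ncol(tab)), function(j) {
    t22 <- cbind(tab[, j], rowSums(tab) - tab[, j])
    ft <- fisher_exact_2x2(t22)
    tibble(
      event_type = colnames(tab)[j],
      n_a = tab[1, j], n_b = tab[2, j],
      odds_ratio = ft$odds_ratio, p = ft$p_value
    )
  })
  per_category$p_adj <- p.adjust(per_category$p, method = "BH")
  structure(
    list(overall_p = overall_p, method = method,
         per_category = per_category),
    class = "event_type_comparison"
  )
}

#' @export
print.event_type_comparison <- function(x, ...) {
  cat(sprintf("Event-type distribution comparison (%s): overall p = %.4g\n",
              x$method, x$overall_p))
  print(x$per_category)
  invisible(x)
}

#' @export
tidy.event_type_comparison <- function(x, ...) x$per_category

#' @export
glance.event_type_comparison <- function(x, ...) {
  tibble(overall_p = x$overall_p, method = x$method)
}
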