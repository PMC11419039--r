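#' Build a ranked gene list from differential-expression results
#'
#' Rows with adjusted p below `padj_max` (default 0.05) are kept and scored
#' by their signed log2 fold change; duplicate genes are resolved by the
#' entry with the largest |log2FC|. The list is sorted by score descending,
#' ties broken by gene symbol for determinism.
#'
#' @param de Tibble with columns `gene`, `log2fc` (aliases `log2FC` and
#'   `log2FoldChange` accepted) and `padj`.
#' @param padj_max Adjusted-p filter.
#' @return A tibble of class `ranked_list` (`gene`, `score`).
#' @export
build_rank_from_expression <- function(de, padj_max = 0.05) {
  nm <- names(de)
  fc_col <- intersect(c("log2fc", "log2FC", "log2FoldChange"), nm)[1]
  if (is.na(fc_col)) abort("`de` needs a log2 fold-change column")
  assert_columns(de, c("gene", "padj"), "de")
  kept <- de[!is.na(de$padj) & de$padj < padj_max, ]
  if (nrow(kept) == 0) {
    warn("no gene passed the adjusted-p filter; returning an empty list")
    return(new_ranked_list(tibble(gene = character(0), score = numeric(0))))
  }
  out <- tibble(gene = kept$gene, score = kept[[fc_col]]) |>
    dplyr::arrange(.data$gene, dplyr::desc(abs(.data$score))) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  new_ranked_list(out)
}

#' Build a ranked gene list from differential-splicing results
#'
#' Events with adjusted p below `padj_max` (default 0.25) are kept and
#' scored by |dPSI|; since a gene can host several events, each gene keeps
#' the entry with the highest |dPSI|. Events without a gene symbol are
#' dropped and their number reported.
#'
#' @param ds A [compare_groups()] result (needs `gene`, `delta_psi`,
#'   `p_adj`).
#' @param padj_max Adjusted-p filter.
#' @return A tibble of class `ranked_list` (`gene`, `score`); all scores
#'   are non-negative.
#' @export
build_rank_from_splicing <- function(ds, padj_max = 0.25) {
  assert_columns(ds, c("gene", "delta_psi", "p_adj"), "ds")
  blank <- is.na(ds$gene) | ds$gene == ""
  if (any(blank)) {
    inform(sprintf("%d event(s) without gene symbol dropped", sum(blank)))
    ds <- ds[!blank, ]
  }
  kept <- ds[!is.na(ds$p_adj) & ds$p_adj < padj_max, ]
  if (nrow(kept) == 0) {
    warn("no event passed the adjusted-p filter; returning an empty list")
    return(new_ranked_list(tibble(gene = character(0), score = numeric(0))))
  }
  out <- tibble(gene = kept$gene, score = abs(kept$delta_psi)) |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$score)) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  new_ranked_list(out)
}

new_ranked_list <- function(df) {
  assert_columns(df, c("gene", "score"), "ranked list")
  if (anyDuplicated(df$gene)) abort("ranked list genes must be unique")
  if (any(is.na(df$score))) abort("ranked list scores must not be missing")
  out <- dplyr::arrange(df, dplyr::desc(.data$score), .data$gene)
  structure(as_tibble(out), class = c("ranked_list", class(out)))
}

#' @rdname build_rank_from_expression
#' @param x A data frame with `gene` and `score` columns to validate and
#'   sort as a ranked list.
#' @export
as_ranked_list <- function(x) {
  if (inherits(x, "ranked_list")) return(x)
  new_ranked_list(as_tibble(x))
}

# Running-sum enrichment score evaluated only at hit boundaries. `a` is the
# full |score|^weight vector over the ranked list. O(n_hits log n_hits).
es_from_hits <- function(a, hit_pos, n) {
  m <- length(hit_pos)
  if (m == 0) return(NA_real_)
  hp <- sort.int(hit_pos)
  ah <- a[hp]
  s <- sum(ah)
  w <- if (s > 0) ah / s else rep(1 / m, m)
  cw <- cumsum(w)
  d <- if (m < n) 1 / (n - m) else 0
  gap <- hp - seq_len(m)
  tops <- cw - d * gap
  bots <- c(0, cw[-m]) - d * gap
  mx <- max(tops, 0)
  mn <- min(bots, 0)
  if (mx >= -mn) mx else mn
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom: at each member ("hit") of the
#' gene set the running sum increases by that gene's weighted score share
#' (|score|^weight normalized over the set's hits); at each non-member it
#' decreases by 1/(N - n_hits). The enrichment score is the signed maximum
#' deviation of the running sum from zero; when the positive and negative
#' excursions tie in magnitude the positive one is reported. A set covering
#' the entire list has no misses, so its monotone walk yields ES = 1.
#'
#' @param ranked A [as_ranked_list()]-compatible table.
#' @param gene_set Character vector of gene symbols.
#' @param weight Score exponent; 1 (default) is the weighted statistic,
#'   0 the classic Kolmogorov-Smirnov walk.
#' @return A list of class `es_profile`: `es`, `n_hits`, `evaluable`, and
#'   `profile` (tibble of rank, gene, hit flag and running sum).
#' @examples
#' rl <- as_ranked_list(tibble::tibble(
#'   gene = c("g1", "g2", "g3", "g4"), score = c(3, 2, 1, 0.5)
#' ))
#' enrichment_score(rl, c("g1"))$es # 1
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  ranked <- as_ranked_list(ranked)
  n <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) {
    return(structure(
      list(es = NA_real_, n_hits = 0L, evaluable = FALSE, profile = NULL),
      class = "es_profile"
    ))
  }
  a <- abs(ranked$score)^weight
  m <- sum(hit)
  s <- sum(a[hit])
  step <- numeric(n)
  step[hit] <- if (s > 0) a[hit] / s else 1 / m
  if (m < n) step[!hit] <- -1 / (n - m)
  running <- cumsum(step)
  mx <- max(running, 0)
  mn <- min(running, 0)
  es <- if (mx >= -mn) mx else mn
  structure(
    list(
      es = es, n_hits = m, evaluable = TRUE,
      profile = tibble(rank = seq_len(n), gene = ranked$gene, hit = hit,
                       running = running)
    ),
    class = "es_profile"
  )
}

#' @export
print.es_profile <- function(x, ...) {
  if (!x$evaluable) {
    cat("<es_profile> not evaluable (no overlap with ranked list)\n")
  } else {
    cat(sprintf("<es_profile> ES = %.4f over %d hits\n", x$es, x$n_hits))
  }
  invisible(x)
}

#' Preranked gene-set enrichment with a permutation null
#'
#' For each gene set, the enrichment score of [enrichment_score()] is
#' compared against a null built by gene-label permutation: size-matched
#' random sets drawn from the ranked universe (the only null available to
#' preranked input). The nominal p uses the add-one estimator over
#' same-sign null scores, NES divides ES by the mean same-sign null |ES|,
#' and the FDR q follows the permutation method — the tail ratio of the
#' pooled normalized null distribution to the observed NES distribution,
#' computed separately for positive and negative NES and clipped to
#' \[0, 1\]. A BH-on-nominal-p alternative is available via `fdr_method`.
#'
#' Null draws are seeded per distinct set size from the master seed, so
#' results do not depend on the order of the gene-set collection.
#'
#' @param ranked A ranked list.
#' @param sets Named list of gene-symbol vectors (a gene-set collection).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Master seed for the permutation streams.
#' @param weight Score exponent passed to the ES walk.
#' @param fdr_method `"permutation"` (default) or `"bh"`.
#' @return A tibble of class `gsea_result`: `set`, `size`, `n_hits`, `es`,
#'   `nes`, `p_nominal`, `fdr_q`, `evaluable`.
#' @examples
#' \donttest{
#' rl <- as_ranked_list(tibble::tibble(
#'   gene = sprintf("G%03d", 1:200), score = sort(rnorm(200), TRUE)
#' ))
#' sets <- list(top = sprintf("G%03d", 1:15), rnd = sprintf("G%03d", 50:70))
#' gsea_preranked(rl, sets, n_perm = 200, seed = 7)
#' }
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed = 1L,
                           weight = 1,
                           fdr_method = c("permutation", "bh")) {
  fdr_method <- match.arg(fdr_method)
  ranked <- as_ranked_list(ranked)
  n <- nrow(ranked)
  if (n == 0) abort("the ranked list is empty")
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list of gene vectors")
  }
  if (any(lengths(sets) == 0)) abort("gene sets must be non-empty")
  if (any(lengths(sets) > n)) {
    abort("a gene set is larger than the ranked universe")
  }
  if (!is_scalar_number(n_perm) || n_perm < 100) {
    abort("`n_perm` must be at least 100")
  }
  n_perm <- as.integer(n_perm)
  a <- abs(ranked$score)^weight

  hits <- lapply(sets, function(s) which(ranked$gene %in% s))
  n_hits <- lengths(hits)
  evaluable <- n_hits > 0
  es_obs <- rep(NA_real_, length(sets))
  es_obs[evaluable] <- vapply(hits[evaluable], es_from_hits, numeric(1),
                              a = a, n = n)

  sizes <- sort(unique(n_hits[evaluable]))
  null_es <- lapply(sizes, function(sz) {
    with_sub_seed(seed, sz, {
      vapply(seq_len(n_perm),
             function(i) es_from_hits(a, sample.int(n, sz), n),
             numeric(1))
    })
  })
  names(null_es) <- as.character(sizes)

  res <- purrr::map_dfr(seq_along(sets), function(i) {
    if (!evaluable[i]) {
      return(tibble(set = names(sets)[i], size = lengths(sets)[i],
                    n_hits = 0L, es = NA_real_, nes = NA_real_,
                    p_nominal = NA_real_, fdr_q = NA_real_,
                    evaluable = FALSE))
    }
    null <- null_es[[as.character(n_hits[i])]]
    es <- es_obs[i]
    pos <- null[null >= 0]
    neg <- null[null < 0]
    if (es >= 0) {
      nes <- if (length(pos) > 0 && mean(pos) > 0) es / mean(pos) else NA_real_
      p <- (1 + sum(pos >= es)) / (1 + length(pos))
    } else {
      mabs <- mean(abs(neg))
      nes <- if (length(neg) > 0 && mabs > 0) es / mabs else NA_real_
      p <- (1 + sum(abs(neg) >= abs(es))) / (1 + length(neg))
    }
    tibble(set = names(sets)[i], size = lengths(sets)[i],
           n_hits = as.integer(n_hits[i]), es = es, nes = nes,
           p_nominal = p, fdr_q = NA_real_, evaluable = TRUE)
  })

  ok <- res$evaluable & !is.na(res$nes)
  if (fdr_method == "bh") {
    res$fdr_q[ok] <- p.adjust(res$p_nominal[ok], method = "BH")
  } else if (any(ok)) {
    # pooled null NES: each null ES normalized by its set's same-sign mean
    pooled <- unlist(lapply(which(ok), function(i) {
      null <- null_es[[as.character(res$n_hits[i])]]
      pos <- null[null >= 0]
      neg <- null[null < 0]
      mp <- if (length(pos) > 0) mean(pos) else NA_real_
      mn <- if (length(neg) > 0) mean(abs(neg)) else NA_real_
      out <- ifelse(null >= 0, null / mp, null / mn)
      out[is.finite(out)]
    }), use.names = FALSE)
    obs <- res$nes[ok]
    res$fdr_q[ok] <- vapply(obs, function(nes) {
      if (nes >= 0) {
        n_null_side <- sum(pooled >= 0)
        n_obs_side <- sum(obs >= 0)
        if (n_null_side == 0 || n_obs_side == 0) return(NA_real_)
        num <- sum(pooled >= nes) / n_null_side
        den <- sum(obs >= nes) / n_obs_side
      } else {
        n_null_side <- sum(pooled < 0)
        n_obs_side <- sum(obs < 0)
        if (n_null_side == 0 || n_obs_side == 0) return(NA_real_)
        num <- sum(pooled <= nes) / n_null_side
        den <- sum(obs <= nes) / n_obs_side
      }
      min(1, max(0, num / den))
    }, numeric(1))
  }

  structure(res, class = c("gsea_result", class(res)),
            n_perm = n_perm, seed = seed, weight = weight,
            fdr_method = fdr_method)
}

#' @export
tidy.gsea_result <- function(x, ...) {
  out <- x
  attributes(out)[c("n_perm", "seed", "weight", "fdr_method")] <- NULL
  class(out) <- setdiff(class(out), "gsea_result")
  as_tibble(out)
}

#' @export
glance.gsea_result <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_evaluable = sum(x$evaluable),
    n_significant = sum(x$fdr_q < 0.25 & x$p_nominal < 0.05, na.rm = TRUE),
    n_perm = attr(x, "n_perm"),
    seed = attr(x, "seed"),
    fdr_method = attr(x, "fdr_method")
  )
}

#' Reporting filter for enrichment results
#'
#' Keeps an NES where the FDR q-value is below `q_max` and the nominal p is
#' below `p_max`; every other cell of the comparisons-by-sets matrix is set
#' to 0 (the convention used when heat-mapping NES across comparisons).
#'
#' @param results A single `gsea_result`, a named list of them (one per
#'   comparison), or a combined tibble with a `comparison` column.
#' @param q_max,p_max Reporting thresholds (defaults 0.25 and 0.05).
#' @return A tibble of class `nes_matrix`: one row per comparison, one
#'   column per gene set.
#' @export
filter_enrichment <- function(results, q_max = 0.25, p_max = 0.05) {
  if (inherits(results, "gsea_result")) {
    results <- list(comparison = results)
  }
  if (is.data.frame(results)) {
    assert_columns(results, c("comparison", "set", "nes", "p_nominal",
                              "fdr_q"), "results")
    df <- as_tibble(results)
  } else {
    df <- dplyr::bind_rows(lapply(results, tidy), .id = "comparison")
  }
  if (nrow(df) == 0) {
    return(structure(tibble(comparison = character(0)),
                     class = c("nes_matrix", "tbl_df", "tbl", "data.frame")))
  }
  pass <- !is.na(df$fdr_q) & !is.na(df$p_nominal) &
    df$fdr_q < q_max & df$p_nominal < p_max
  df$value <- ifelse(pass & !is.na(df$nes), df$nes, 0)
  wide <- tidyr::pivot_wider(df[c("comparison", "set", "value")],
                             names_from = "set", values_from = "value",
                             values_fill = 0)
  structure(wide, class = c("nes_matrix", class(wide)))
}

#' Restrict a gene set by an evidence list
#'
#' Intersection preserving the order of the first set — e.g. restricting a
#' stress-granule protein set to genes with differential RNA binding.
#'
#' @param set_a Character vector (ordered gene set).
#' @param evidence_genes Character vector to intersect with.
#' @return The ordered intersection; warns when empty.
#' @export
restrict_gene_set <- function(set_a, evidence_genes) {
  if (length(set_a) == 0 || length(evidence_genes) == 0) {
    abort("both gene lists must be non-empty")
  }
  out <- set_a[set_a %in% evidence_genes]
  if (length(out) == 0) warn("the restricted gene set is empty")
  inform(sprintf("restricted set: %d of %d genes retained",
                 length(out), length(set_a)))
  out
}

#' Ranked-list and gene-set file formats
#'
#' RNK: two tab-separated columns (gene, score), no header. GMT: one set
#' per line — name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @param ranked A ranked list for `write_rnk()`.
#' @param sets Named list of gene vectors for `write_gmt()`.
#' @param descriptions Optional per-set description column for GMT output.
#' @export
read_rnk <- function(path) {
  df <- readr::read_tsv(path, col_names = c("gene", "score"),
                        col_types = "cd", progress = FALSE)
  new_ranked_list(df)
}

#' @rdname read_rnk
#' @export
write_rnk <- function(ranked, path) {
  ranked <- as_ranked_list(ranked)
  readr::write_tsv(ranked[c("gene", "score")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname read_rnk
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_rnk
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) abort("`sets` must be named")
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
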