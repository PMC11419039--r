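#' Volcano-style view of a differential-splicing result
#'
#' @param object A [compare_groups()] result.
#' @param ... Ignored.
#' @return A ggplot object: dPSI against -log10 adjusted p, significant
#'   events highlighted.
#' @export
autoplot.diff_splicing <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$tested, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta_psi, y = -log10(.data$p_adj),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * attr(object, "dpsi_min"), linetype = 2
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(attr(object, "padj_max")), linetype = 2
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "ΔPSI (test - reference)", y = "-log10 adjusted p",
      colour = "significant",
      title = sprintf("%s vs %s", attr(object, "test_group"),
                      attr(object, "ref_group"))
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of a splicing event-type distribution
#'
#' @param dist An [event_type_distribution()].
#' @return A ggplot object.
#' @export
plot_event_type_distribution <- function(dist) {
  if (!inherits(dist, "event_type_distribution")) {
    abort("`dist` must come from event_type_distribution()")
  }
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$event_type, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "significant events",
                  title = attr(dist, "label")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-sample alteration burden
#'
#' @param object A [sample_burden()] result.
#' @param meta Optional metadata with `sample_id` and `group` for fill
#'   colour.
#' @param ... Ignored.
#' @return A ggplot object with samples ordered by burden.
#' @export
autoplot.burden_profile <- function(object, meta = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(meta)) df <- dplyr::left_join(df, meta, by = "sample_id")
  df$sample_id <- stats::reorder(df$sample_id, df$burden)
  aes <- if ("group" %in% names(df)) {
    ggplot2::aes(x = .data$sample_id, y = .data$burden, fill = .data$group)
  } else {
    ggplot2::aes(x = .data$sample_id, y = .data$burden)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "altered splicing events") +
    ggplot2::theme_minimal()
}

#' NES overview of an enrichment run
#'
#' @param object A [gsea_preranked()] result.
#' @param q_max Highlight threshold on the FDR q-value.
#' @param ... Ignored.
#' @return A ggplot object: NES per gene set, enriched sets highlighted.
#' @export
autoplot.gsea_result <- function(object, q_max = 0.25, ...) {
  df <- tidy(object)
  df <- df[df$evaluable & !is.na(df$nes), ]
  df$set <- stats::reorder(df$set, df$nes)
  df$pass <- !is.na(df$fdr_q) & df$fdr_q < q_max
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$set,
                                   fill = .data$pass)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "darkorange")) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL,
                  fill = sprintf("FDR q < %.2g", q_max)) +
    ggplot2::theme_minimal()
}

#' Heatmap of filtered NES across comparisons
#'
#' @param object A [filter_enrichment()] matrix.
#' @param ... Ignored.
#' @return A ggplot tile plot; cells failing the reporting filter are 0.
#' @export
autoplot.nes_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"comparison",
                              names_to = "set", values_to = "nes")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$comparison, y = .data$set,
                                     fill = .data$nes)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "NES") +
    ggplot2::theme_minimal()
}

#' Running enrichment-score profile
#'
#' @param profile An [enrichment_score()] result.
#' @return A ggplot line plot of the running sum with hit positions marked.
#' @export
plot_running_es <- function(profile) {
  if (!inherits(profile, "es_profile") || !profile$evaluable) {
    abort("`profile` must be an evaluable es_profile")
  }
  df <- profile$profile
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_rug(data = df[df$hit, ], sides = "b") +
    ggplot2::labs(x = "rank", y = "running enrichment score") +
    ggplot2::theme_minimal()
}
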