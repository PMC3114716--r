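#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a running-sum profile
#'
#' The mountain/valley view of the unweighted GSEA statistic: the running
#' sum along the ranked list, with the maximal absolute deviation D marked
#' and member positions shown as a rug. A mountain-like profile (positive
#' maximum) indicates enrichment toward the top of the list, a valley-like
#' one depletion.
#'
#' @param object A `trail_running_sum` from [running_sum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trail_running_sum
#' @export
autoplot.trail_running_sum <- function(object, ...) {
  df <- tibble::tibble(rank = seq_len(object$n), rs = object$rs)
  at_max <- which(abs(object$rs) == object$D)[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$rs)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = if (object$sign == "+") "firebrick" else "forestgreen") +
    ggplot2::geom_point(
      data = df[at_max, , drop = FALSE], size = 2,
      colour = if (object$sign == "+") "firebrick" else "forestgreen"
    ) +
    ggplot2::geom_rug(
      data = tibble::tibble(rank = object$positions),
      ggplot2::aes(x = .data$rank), inherit.aes = FALSE, sides = "b",
      length = ggplot2::unit(0.03, "npc")
    ) +
    ggplot2::labs(
      x = "rank in list", y = "running sum",
      title = sprintf(
        "n = %d, k = %d, D = %s (%s)", object$n, object$k,
        format(object$D), if (object$sign == "+") "enriched" else "depleted"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot enrichment results as a significance bar chart
#'
#' Categories ordered by adjusted p-value, bars showing -log10(p_adj),
#' coloured by direction, with the significance threshold drawn as a dashed
#' line.
#'
#' @param object A `trail_gsea` or `trail_ora` object after
#'   [adjust_significance()].
#' @param top Number of categories shown (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trail_gsea
#' @export
autoplot.trail_gsea <- function(object, top = 20, ...) {
  plot_enrichment(object, top = top)
}

#' @rdname autoplot.trail_gsea
#' @method autoplot trail_ora
#' @export
autoplot.trail_ora <- function(object, top = 20, ...) {
  plot_enrichment(object, top = top)
}

#' @rdname autoplot.trail_gsea
#' @param results Enrichment tibble with `category`, `direction`, `p_adj`.
#' @export
plot_enrichment <- function(results, top = 20) {
  stopifnot(all(c("category", "direction", "p_adj") %in% names(results)))
  alpha <- attr(results, "alpha") %||% 0.05
  df <- tibble::as_tibble(as.data.frame(results)) |>
    dplyr::arrange(.data$p_adj) |>
    dplyr::slice_head(n = top) |>
    dplyr::mutate(category = stats::reorder(.data$category, -.data$p_adj))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$p_adj, 1e-300)), y = .data$category,
    fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(
      "enriched" = "firebrick", "over-represented" = "firebrick",
      "depleted" = "forestgreen", "under-represented" = "forestgreen"
    )) +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-comparison induced/repressed counts
#'
#' Bar-chart rendering of [count_table()]: one stacked bar per comparison,
#' split by regulation direction.
#'
#' @param mat A `trail_comparison_matrix` from [run_comparisons()].
#' @return A ggplot object.
#' @export
plot_comparison_counts <- function(mat) {
  ct <- count_table(mat)
  df <- ct |>
    tidyr::pivot_longer(c("induced", "repressed"),
      names_to = "regulation", values_to = "count"
    ) |>
    dplyr::mutate(comparison = factor(.data$comparison, levels = rev(ct$comparison)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$count, y = .data$comparison, fill = .data$regulation
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      induced = "firebrick", repressed = "forestgreen"
    )) +
    ggplot2::labs(x = "significant categories", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
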