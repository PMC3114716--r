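#' Run GSEA across a set of pairwise comparisons
#'
#' The reporting driver: for each comparison spec, ranks genes by fold
#' change from the condition medians, runs the unweighted GSEA over the
#' category collection, and applies FDR within the run. A significant
#' category enriched toward the top of the test-vs-baseline ranking is
#' called "induced", one depleted toward the bottom "repressed".
#'
#' @param medians Condition tibble from [replicate_median()].
#' @param categories Category tibble.
#' @param specs Comparison tibble (default [default_comparisons()]: the
#'   study-shaped eight).
#' @param min_size,alpha GSEA minimum category size and FDR threshold
#'   (defaults 2 and 0.05, the study's settings).
#' @param pseudocount Passed to [fold_change_ranking()].
#' @return A `trail_comparison_matrix` tibble with one row per
#'   (comparison, category): columns `comparison`, `category`, `k`, `D`,
#'   `p_value`, `p_adj`, `significant`, `regulation` (`"induced"`,
#'   `"repressed"`, or NA for non-significant cells). The `specs` attribute
#'   keeps the comparison order.
#' @export
run_comparisons <- function(medians, categories, specs = default_comparisons(),
                            min_size = 2, alpha = 0.05, pseudocount = 0) {
  stopifnot(nrow(specs) >= 1L)
  rows <- purrr::pmap(specs, function(...) {
    spec <- tibble::tibble(...)
    ranked <- fold_change_ranking(medians, spec, pseudocount = pseudocount)
    res <- gsea_test(ranked, categories, min_size = min_size) |>
      adjust_significance(alpha = alpha)
    tibble::tibble(
      comparison = spec$comparison,
      category = res$category, k = res$k, D = res$D,
      p_value = res$p_value, p_adj = res$p_adj,
      significant = res$significant,
      regulation = dplyr::if_else(
        res$significant,
        dplyr::if_else(res$direction == "enriched", "induced", "repressed"),
        NA_character_
      )
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(
      match(.data$comparison, specs$comparison), .data$category
    )
  structure(out,
    class = c("trail_comparison_matrix", class(tibble::tibble())),
    specs = specs, alpha = alpha
  )
}

#' Venn-region summary of significant categories
#'
#' Assigns every significant category to the disjoint region given by the
#' exact set of comparisons in which it is significant, recording the
#' per-comparison regulation mark (a category may be induced in one
#' comparison and repressed in another; marks are rendered as `+`/`-`
#' suffixes). Regions partition the significant categories: each category
#' appears in exactly one region and region sizes sum to the number of
#' distinct significant categories.
#'
#' @param mat A `trail_comparison_matrix` from [run_comparisons()].
#' @return A tibble with one row per significant category: `category`,
#'   `region` (comparison labels joined with `" & "`, in configured order),
#'   `n_comparisons`, `marks` (per-comparison `label+`/`label-` marks,
#'   `; `-joined), and a list-column `comparisons`.
#' @export
venn_summary <- function(mat) {
  stopifnot(all(c("comparison", "category", "significant") %in% names(mat)))
  specs <- attr(mat, "specs")
  order_lv <- if (!is.null(specs)) specs$comparison else unique(mat$comparison)
  sig <- mat[mat$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(tibble::tibble(
      category = character(), region = character(),
      n_comparisons = integer(), marks = character(),
      comparisons = list()
    ))
  }
  sig |>
    dplyr::mutate(comparison = factor(.data$comparison, levels = order_lv)) |>
    dplyr::arrange(.data$comparison) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      region = paste(as.character(.data$comparison), collapse = " & "),
      n_comparisons = dplyr::n(),
      marks = paste0(
        as.character(.data$comparison),
        dplyr::if_else(.data$regulation == "induced", "+", "-"),
        collapse = "; "
      ),
      comparisons = list(as.character(.data$comparison)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$region, .data$category)
}

#' Per-comparison counts of induced and repressed categories
#'
#' The count-table view: for every comparison, how many significant
#' categories were induced, how many repressed, and their sum. When an
#' optional category-to-area mapping is supplied, the number of distinct
#' areas covered is reported alongside (the parenthesized style of grouped
#' count tables).
#'
#' @param mat A `trail_comparison_matrix` from [run_comparisons()].
#' @param areas Optional two-column data frame (`category`, `area`) mapping
#'   categories to higher-level areas.
#' @return A tibble with one row per comparison (in configured order):
#'   `comparison`, `induced`, `repressed`, `total`, and `areas` when a
#'   mapping was given.
#' @export
count_table <- function(mat, areas = NULL) {
  stopifnot(all(c("comparison", "significant", "regulation") %in% names(mat)))
  specs <- attr(mat, "specs")
  order_lv <- if (!is.null(specs)) specs$comparison else unique(mat$comparison)
  base <- tibble::tibble(comparison = order_lv)
  counts <- mat |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(
      induced = sum(.data$regulation == "induced"),
      repressed = sum(.data$regulation == "repressed"),
      total = dplyr::n(),
      .groups = "drop"
    )
  out <- dplyr::left_join(base, counts, by = "comparison") |>
    dplyr::mutate(dplyr::across(
      c("induced", "repressed", "total"),
      ~ tidyr::replace_na(.x, 0L)
    ))
  if (!is.null(areas)) {
    stopifnot(all(c("category", "area") %in% names(areas)))
    area_counts <- mat |>
      dplyr::filter(.data$significant) |>
      dplyr::inner_join(areas, by = "category") |>
      dplyr::group_by(.data$comparison) |>
      dplyr::summarise(areas = dplyr::n_distinct(.data$area), .groups = "drop")
    out <- dplyr::left_join(out, area_counts, by = "comparison") |>
      dplyr::mutate(areas = tidyr::replace_na(.data$areas, 0L))
  }
  out
}
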