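#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an enrichment or differential-expression result
#'
#' The result tables are already tibbles; `tidy()` strips the result class
#' and attributes so the rows can be bound and reshaped freely, adding the
#' comparison label as a column when one is attached.
#'
#' @param x A `trail_gsea`, `trail_ora`, or `trail_de` object.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy trail_gsea
#' @export
tidy.trail_gsea <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x))
  cmp <- attr(x, "comparison")
  if (!is.null(cmp)) out <- dplyr::mutate(out, comparison = cmp, .before = 1)
  out
}

#' @rdname tidy.trail_gsea
#' @method tidy trail_ora
#' @export
tidy.trail_ora <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.trail_gsea
#' @method tidy trail_de
#' @export
tidy.trail_de <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x))
  cmp <- attr(x, "comparison")
  if (!is.null(cmp)) out <- dplyr::mutate(out, comparison = cmp, .before = 1)
  out
}

#' One-row summary of an enrichment or differential-expression result
#'
#' @param x A `trail_gsea`, `trail_ora`, or `trail_de` object (for the
#'   enrichment types, ideally after [adjust_significance()]).
#' @param ... Unused.
#' @return A one-row tibble: number of categories (or genes) tested, number
#'   significant, the smallest raw p, and the settings recorded on the
#'   object.
#' @method glance trail_gsea
#' @export
glance.trail_gsea <- function(x, ...) {
  tibble::tibble(
    comparison = attr(x, "comparison") %||% NA_character_,
    n_categories = nrow(x),
    n_significant = if ("significant" %in% names(x)) sum(x$significant) else NA_integer_,
    min_p = if (nrow(x)) min(x$p_value) else NA_real_,
    min_size = attr(x, "min_size") %||% NA_real_,
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' @rdname glance.trail_gsea
#' @method glance trail_ora
#' @export
glance.trail_ora <- function(x, ...) {
  tibble::tibble(
    n_categories = nrow(x),
    n_significant = if ("significant" %in% names(x)) sum(x$significant) else NA_integer_,
    min_p = if (nrow(x)) min(x$p_value) else NA_real_,
    reference_size = if (nrow(x)) x$m[[1]] else NA_integer_,
    test_size = if (nrow(x)) x$t[[1]] else NA_integer_,
    min_size = attr(x, "min_size") %||% NA_real_,
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' @rdname glance.trail_gsea
#' @method glance trail_de
#' @export
glance.trail_de <- function(x, ...) {
  st <- attr(x, "settings")
  tibble::tibble(
    comparison = attr(x, "comparison") %||% NA_character_,
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_,
    error_model = if (!is.null(st)) st$error_model else NA_character_,
    prior_df = if (!is.null(st)) st$prior_df else NA_real_,
    fdr_alpha = if (!is.null(st)) st$fdr_alpha else NA_real_
  )
}
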