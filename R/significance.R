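#' Benjamini-Hochberg step-up adjustment
#'
#' Returns the step-up adjusted values
#' `q_(i) = min_{j >= i}(m * p_(j) / j)` capped at 1, in input order.
#' Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04)) # 0.03 0.03 0.04
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Attach FDR-adjusted p-values and significance calls
#'
#' Adjusts the raw p-values of an enrichment result table across all its
#' categories (one FDR family per analysis run) and flags those with adjusted
#' p at or below `alpha`. The threshold comparison is inclusive.
#'
#' @param results A `trail_gsea` or `trail_ora` tibble (any tibble with a
#'   `p_value` column works).
#' @param alpha Significance threshold on the adjusted scale (default 0.05).
#' @param method `"fdr"` (Benjamini-Hochberg, default) or `"none"` (the raw
#'   p-values are copied and thresholded directly).
#' @return The input tibble with columns `p_adj` and `significant` appended;
#'   attributes `alpha` and `adjust_method` record the settings.
#' @export
adjust_significance <- function(results, alpha = 0.05, method = c("fdr", "none")) {
  method <- match.arg(method)
  stopifnot("p_value" %in% names(results), alpha >= 0, alpha <= 1)
  results$p_adj <- if (method == "fdr") bh_adjust(results$p_value) else results$p_value
  results$significant <- results$p_adj <= alpha
  attr(results, "alpha") <- alpha
  attr(results, "adjust_method") <- method
  results
}
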