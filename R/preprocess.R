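#' Scale each sample to a target mean signal
#'
#' Multiplies every sample column by `target / mean(column)` so that the
#' average overall signal intensity of all probe sets equals `target` (100 in
#' the MAS-style convention) in every sample.
#'
#' @param exprs Expression tibble: first column `gene`, one numeric column
#'   per sample.
#' @param target Positive target mean signal (default 100).
#' @return The scaled expression tibble; every sample column has mean
#'   `target` to within relative 1e-9.
#' @export
scale_to_target <- function(exprs, target = 100) {
  check_exprs(exprs)
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  samples <- setdiff(names(exprs), "gene")
  means <- vapply(exprs[samples], mean, numeric(1))
  if (any(means <= 0)) {
    stop("sample(s) with non-positive mean signal: ",
      paste(samples[means <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  exprs[samples] <- purrr::map2(exprs[samples], means, function(x, m) x * (target / m))
  exprs
}

#' Quantile-normalize an expression matrix
#'
#' Forces all sample columns to share one empirical distribution: the vector
#' of row means of the column-sorted values, each value placed back at its
#' column's original rank. Ties within a column receive the mean of the
#' quantile values they span, so the transform is deterministic and
#' idempotent. Delegates to [limma::normalizeQuantiles()].
#'
#' @inheritParams scale_to_target
#' @return The normalized expression tibble. After normalization the sorted
#'   value vector is identical across samples (up to tie averaging).
#' @export
quantile_normalize <- function(exprs) {
  check_exprs(exprs)
  samples <- setdiff(names(exprs), "gene")
  if (length(samples) < 2L) {
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  }
  m <- as.matrix(exprs[samples])
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  exprs[samples] <- tibble::as_tibble(norm, .name_repair = "minimal")
  exprs
}

#' Summarize replicates by condition medians
#'
#' For each gene and each distinct (tissue, genotype, treatment) condition in
#' the design, takes the median of that condition's replicate signals (the
#' study used n = 3 biological replicates per condition).
#'
#' @inheritParams scale_to_target
#' @param design Design tibble with columns `sample`, `tissue`, `genotype`,
#'   `treatment` (and optionally `replicate`); `sample` must cover the
#'   expression columns.
#' @return A long condition tibble with columns `gene`, `tissue`, `genotype`,
#'   `treatment`, `median`.
#' @export
replicate_median <- function(exprs, design) {
  check_exprs(exprs)
  need <- c("sample", "tissue", "genotype", "treatment")
  if (!all(need %in% names(design))) {
    stop("design must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  samples <- setdiff(names(exprs), "gene")
  missing <- setdiff(samples, design$sample)
  if (length(missing) > 0L) {
    stop("samples missing from design: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  exprs |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "signal") |>
    dplyr::inner_join(design[need], by = "sample") |>
    dplyr::group_by(.data$gene, .data$tissue, .data$genotype, .data$treatment) |>
    dplyr::summarise(median = stats::median(.data$signal), .groups = "drop")
}

#' Define a pairwise comparison
#'
#' A comparison contrasts a test condition against a baseline condition
#' within one tissue; the ranked list it induces scores each gene by the
#' log2 ratio of its test median over its baseline median.
#'
#' @param tissue Tissue the comparison is restricted to.
#' @param test,baseline Named character vectors giving `genotype` and
#'   `treatment` of the test and baseline condition.
#' @param label Optional label; defaults to
#'   `"<tissue>: <test> vs <baseline>"`.
#' @return A one-row tibble describing the comparison.
#' @export
#' @examples
#' comparison_spec("root",
#'   test = c(genotype = "WT", treatment = "-Fe"),
#'   baseline = c(genotype = "WT", treatment = "+Fe")
#' )
comparison_spec <- function(tissue, test, baseline, label = NULL) {
  stopifnot(
    all(c("genotype", "treatment") %in% names(test)),
    all(c("genotype", "treatment") %in% names(baseline))
  )
  if (identical(test[c("genotype", "treatment")], baseline[c("genotype", "treatment")])) {
    stop("test and baseline conditions are identical", call. = FALSE)
  }
  lab <- label %||% sprintf(
    "%s: %s %s vs %s %s", tissue,
    test[["genotype"]], test[["treatment"]],
    baseline[["genotype"]], baseline[["treatment"]]
  )
  tibble::tibble(
    comparison = lab, tissue = tissue,
    test_genotype = test[["genotype"]], test_treatment = test[["treatment"]],
    base_genotype = baseline[["genotype"]], base_treatment = baseline[["treatment"]]
  )
}

#' The study-shaped set of eight pairwise comparisons
#'
#' For each tissue: deficiency vs. sufficiency in each genotype, and mutant
#' vs. wild type under each treatment — the four contrasts that are
#' biologically meaningful in a 2 (genotype) x 2 (treatment) design, taken
#' per tissue.
#'
#' @param tissues Tissues to expand over (default `c("root", "leaf")`).
#' @param genotypes Genotypes, baseline first (default `c("WT", "nas4x-1")`).
#' @param treatments Treatments, baseline first (default `c("+Fe", "-Fe")`).
#' @return A tibble of comparison specs, one row per comparison (8 by
#'   default).
#' @export
default_comparisons <- function(tissues = c("root", "leaf"),
                                genotypes = c("WT", "nas4x-1"),
                                treatments = c("+Fe", "-Fe")) {
  stopifnot(length(genotypes) == 2L, length(treatments) == 2L)
  purrr::map_dfr(tissues, function(ti) {
    dplyr::bind_rows(
      comparison_spec(ti,
        test = c(genotype = genotypes[1], treatment = treatments[2]),
        baseline = c(genotype = genotypes[1], treatment = treatments[1])
      ),
      comparison_spec(ti,
        test = c(genotype = genotypes[2], treatment = treatments[2]),
        baseline = c(genotype = genotypes[2], treatment = treatments[1])
      ),
      comparison_spec(ti,
        test = c(genotype = genotypes[2], treatment = treatments[1]),
        baseline = c(genotype = genotypes[1], treatment = treatments[1])
      ),
      comparison_spec(ti,
        test = c(genotype = genotypes[2], treatment = treatments[2]),
        baseline = c(genotype = genotypes[1], treatment = treatments[2])
      )
    )
  })
}

#' Rank genes by fold change for one comparison
#'
#' Scores each gene by
#' `log2((median_test + pseudocount) / (median_baseline + pseudocount))` and
#' sorts from highest to lowest. Ties are broken lexicographically by gene id
#' so the ranking is fully deterministic.
#'
#' @param medians Condition tibble from [replicate_median()].
#' @param spec One-row comparison tibble from [comparison_spec()].
#' @param pseudocount Non-negative value added to both medians before the
#'   ratio; must be positive if any involved median is zero (default 0: never
#'   silently alter scores).
#' @return A ranked-list tibble with columns `gene` and `score`, sorted by
#'   decreasing score, carrying the comparison label as the `comparison`
#'   attribute.
#' @export
fold_change_ranking <- function(medians, spec, pseudocount = 0) {
  stopifnot(
    is.data.frame(spec), nrow(spec) == 1L,
    all(c("median", "gene") %in% names(medians)),
    pseudocount >= 0
  )
  pick <- function(genotype, treatment) {
    x <- medians |>
      dplyr::filter(
        .data$tissue == spec$tissue,
        .data$genotype == !!genotype,
        .data$treatment == !!treatment
      )
    if (nrow(x) == 0L) {
      stop("condition not present in medians: ",
        paste(spec$tissue, genotype, treatment), call. = FALSE)
    }
    x[c("gene", "median")]
  }
  test <- pick(spec$test_genotype, spec$test_treatment)
  base <- pick(spec$base_genotype, spec$base_treatment)
  joined <- dplyr::inner_join(test, base, by = "gene", suffix = c("_test", "_base"))
  if (pseudocount == 0 && any(joined$median_base == 0 | joined$median_test == 0)) {
    stop("zero median encountered with pseudocount 0; supply a positive pseudocount",
      call. = FALSE
    )
  }
  out <- joined |>
    dplyr::mutate(score = log2((.data$median_test + pseudocount) /
      (.data$median_base + pseudocount))) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene) |>
    dplyr::select("gene", "score")
  if (nrow(out) < 2L) stop("ranked list needs at least 2 genes", call. = FALSE)
  attr(out, "comparison") <- spec$comparison
  out
}

check_exprs <- function(x) {
  if (!is.data.frame(x) || names(x)[1] != "gene" || ncol(x) < 2L) {
    stop("expected an expression tibble with first column 'gene' and one column per sample",
      call. = FALSE
    )
  }
  if (anyNA(x$gene) || anyDuplicated(x$gene)) {
    stop("gene ids must be present and unique", call. = FALSE)
  }
  invisible(x)
}
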