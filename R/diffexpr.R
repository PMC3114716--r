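#' Settings for the regularized per-gene ANOVA selector
#'
#' Defaults reproduce the settings string reported for the NIA-style
#' analysis: error model "max(average, actual)", 0.01 proportion of highest
#' variance values removed before variance averaging, 10 prior degrees of
#' freedom for the Bayesian error model, BH FDR threshold 0.05, and no
#' permutations (parametric F p-values only). The tool's internals are not
#' published; this is a declared reconstruction with every knob exposed.
#'
#' @param error_model `"max_avg_actual"` (default: per-gene error variance is
#'   the larger of the intensity-smoothed average and the gene's own residual
#'   variance), `"actual"` (residual variance only) or `"average"` (smoothed
#'   average only).
#' @param trim_proportion Fraction of the largest variances discarded within
#'   each intensity window before averaging (default 0.01).
#' @param prior_df Prior degrees of freedom pulling the error variance
#'   toward the smoothed average (default 10).
#' @param fdr_alpha BH threshold for the significance flag (default 0.05).
#' @param window_size Number of intensity-ordered neighbours averaged per
#'   window (default 500; windows are clipped at the ends of the intensity
#'   range).
#' @param variance_floor Lower bound applied to the posterior variance so
#'   zero-variance genes yield finite F (default 1e-8).
#' @param log2_transform Log2-transform signals (after adding `log2_offset`)
#'   before the ANOVA, for variance stabilization (default TRUE).
#' @param log2_offset Offset added before the log (default 1).
#' @return A list of settings of class `nia_settings`.
#' @export
nia_settings <- function(error_model = c("max_avg_actual", "actual", "average"),
                         trim_proportion = 0.01, prior_df = 10,
                         fdr_alpha = 0.05, window_size = 500,
                         variance_floor = 1e-8,
                         log2_transform = TRUE, log2_offset = 1) {
  error_model <- match.arg(error_model)
  stopifnot(
    trim_proportion >= 0, trim_proportion < 0.5,
    prior_df >= 0, window_size >= 1, variance_floor > 0
  )
  structure(
    list(
      error_model = error_model, trim_proportion = trim_proportion,
      prior_df = prior_df, fdr_alpha = fdr_alpha, window_size = window_size,
      variance_floor = variance_floor, log2_transform = log2_transform,
      log2_offset = log2_offset
    ),
    class = "nia_settings"
  )
}

#' Intensity-windowed trimmed average of residual variances
#'
#' Orders genes by mean signal intensity and, for each gene, averages the
#' residual variances in a centered window of `window_size` neighbours after
#' discarding the largest `trim_proportion` fraction of variances in that
#' window. Windows are clipped at the ends of the intensity range. This is
#' the "average" error variance the Bayesian error model shrinks toward.
#'
#' @param vars Per-gene residual variances.
#' @param intensities Per-gene mean (log) signal, aligned with `vars`.
#' @param settings A [nia_settings()] object.
#' @return Per-gene smoothed variances in the input gene order.
#' @export
smoothed_variance <- function(vars, intensities, settings = nia_settings()) {
  stopifnot(length(vars) == length(intensities))
  ng <- length(vars)
  if (ng == 0L) return(numeric())
  trim <- settings$trim_proportion
  if (trim > 0 && ng < 1 / trim) {
    warning("fewer genes than 1/trim_proportion; variance trimming skipped",
      call. = FALSE
    )
    trim <- 0
  }
  ord <- order(intensities)
  v <- vars[ord]
  half <- floor(settings$window_size / 2)
  out_sorted <- vapply(seq_len(ng), function(i) {
    lo <- max(1L, i - half)
    hi <- min(ng, i + half)
    w <- v[lo:hi]
    n_drop <- floor(trim * length(w))
    if (n_drop > 0L) w <- sort(w)[seq_len(length(w) - n_drop)]
    mean(w)
  }, numeric(1))
  out <- numeric(ng)
  out[ord] <- out_sorted
  out
}

#' Per-gene two-group ANOVA with a regularized error model
#'
#' For each gene, a single-factor ANOVA of group A versus group B on (by
#' default log2) signals: the between-group mean square is tested against a
#' posterior error variance that shrinks the per-gene estimate toward the
#' intensity-windowed average with `prior_df` prior degrees of freedom,
#'
#' `s2_post = (prior_df * s2_smooth + df_g * s2_err) / (prior_df + df_g)`,
#'
#' where `s2_err` depends on the error model (default: the larger of the
#' smoothed and the per-gene residual variance) and `df_g = nA + nB - 2`.
#' P-values come from the F distribution with `(1, df_g + prior_df)` degrees
#' of freedom and are BH-adjusted across genes.
#'
#' @param exprs Expression tibble (`gene` + sample columns).
#' @param group_a,group_b Character vectors of sample (column) names for the
#'   two groups; at least 2 samples each.
#' @param settings A [nia_settings()] object.
#' @param label Comparison label stored on the result (default derived from
#'   the group names).
#' @return A `trail_de` tibble with one row per gene: `gene`, `mean_a`,
#'   `mean_b`, `intensity`, `var_residual`, `var_smooth`, `var_post`,
#'   `f_stat`, `df1`, `df2`, `p_value`, `p_adj`, `significant`.
#' @export
pairwise_anova <- function(exprs, group_a, group_b,
                           settings = nia_settings(), label = NULL) {
  check_exprs(exprs)
  stopifnot(
    length(group_a) >= 2L, length(group_b) >= 2L,
    all(c(group_a, group_b) %in% names(exprs)),
    length(intersect(group_a, group_b)) == 0L
  )
  a <- as.matrix(exprs[group_a])
  b <- as.matrix(exprs[group_b])
  if (settings$log2_transform) {
    a <- log2(a + settings$log2_offset)
    b <- log2(b + settings$log2_offset)
  }
  na <- ncol(a)
  nb <- ncol(b)
  df_g <- na + nb - 2
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  ss_a <- rowSums((a - mean_a)^2)
  ss_b <- rowSums((b - mean_b)^2)
  s2 <- (ss_a + ss_b) / df_g
  intensity <- (na * mean_a + nb * mean_b) / (na + nb)
  s2_smooth <- smoothed_variance(s2, intensity, settings)
  s2_err <- switch(settings$error_model,
    actual = s2,
    average = s2_smooth,
    max_avg_actual = pmax(s2, s2_smooth)
  )
  pd <- settings$prior_df
  s2_post <- if (pd + df_g > 0) (pd * s2_smooth + df_g * s2_err) / (pd + df_g) else s2_err
  msb <- (na * nb / (na + nb)) * (mean_a - mean_b)^2
  f <- msb / pmax(s2_post, settings$variance_floor)
  df2 <- df_g + pd
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  out <- tibble::tibble(
    gene = exprs$gene, mean_a = mean_a, mean_b = mean_b,
    intensity = intensity, var_residual = s2, var_smooth = s2_smooth,
    var_post = s2_post, f_stat = f, df1 = 1, df2 = df2, p_value = p
  )
  out$p_adj <- bh_adjust(out$p_value)
  out$significant <- out$p_adj <= settings$fdr_alpha
  structure(out,
    class = c("trail_de", class(tibble::tibble())),
    comparison = label %||% paste(
      paste(group_a, collapse = ","), "vs", paste(group_b, collapse = ",")
    ),
    settings = settings, analysis = "de"
  )
}

#' Run the ANOVA selector for every comparison in a design
#'
#' Convenience driver: for each row of `specs`, the samples of the test and
#' baseline condition are looked up in `design` and [pairwise_anova()] is
#' run.
#'
#' @param exprs Expression tibble.
#' @param design Design tibble (`sample`, `tissue`, `genotype`, `treatment`).
#' @param specs Comparison tibble from [default_comparisons()] or
#'   [comparison_spec()].
#' @param settings A [nia_settings()] object.
#' @return A named list of `trail_de` tables, one per comparison, each
#'   carrying its `comparison` and `tissue` attributes.
#' @export
de_comparisons <- function(exprs, design, specs = default_comparisons(),
                           settings = nia_settings()) {
  stopifnot(nrow(specs) >= 1L)
  res <- purrr::pmap(specs, function(comparison, tissue, test_genotype,
                                     test_treatment, base_genotype,
                                     base_treatment, ...) {
    pick <- function(g, tr) {
      s <- design$sample[design$tissue == tissue &
        design$genotype == g & design$treatment == tr]
      if (length(s) < 2L) {
        stop("fewer than 2 samples for condition ", paste(tissue, g, tr),
          call. = FALSE
        )
      }
      s
    }
    tab <- pairwise_anova(exprs,
      group_a = pick(test_genotype, test_treatment),
      group_b = pick(base_genotype, base_treatment),
      settings = settings, label = comparison
    )
    attr(tab, "tissue") <- tissue
    tab
  })
  names(res) <- specs$comparison
  res
}

#' Union of significant genes across comparisons
#'
#' Collects every gene flagged significant in at least one of the supplied
#' per-comparison ANOVA tables (each gene counted once) and partitions the
#' union by the tissue of the comparisons it was significant in — the
#' study's shape of "differentially expressed in at least one pairwise
#' comparison", split into leaf- and root-specific lists.
#'
#' @param tables List of `trail_de` tables from [de_comparisons()] (or
#'   [pairwise_anova()] with a `tissue` attribute set).
#' @return A tibble with columns `gene`, `tissue` (the tissue(s) the gene
#'   was significant in, `"+"`-joined when several) and `n_comparisons`
#'   (number of comparisons flagging it).
#' @export
select_de_union <- function(tables) {
  stopifnot(is.list(tables))
  hits <- purrr::map_dfr(tables, function(tab) {
    stopifnot("significant" %in% names(tab))
    sig <- tab[tab$significant, "gene", drop = FALSE]
    if (nrow(sig) == 0L) {
      return(tibble::tibble(gene = character(), tissue = character()))
    }
    tibble::tibble(gene = sig$gene, tissue = attr(tab, "tissue") %||% NA_character_)
  })
  if (nrow(hits) == 0L) {
    return(tibble::tibble(
      gene = character(), tissue = character(), n_comparisons = integer()
    ))
  }
  hits |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      tissue = paste(sort(unique(stats::na.omit(.data$tissue))), collapse = "+"),
      n_comparisons = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene)
}
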