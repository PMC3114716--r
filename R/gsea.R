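#' Running-sum profile of a category along a ranked list
#'
#' Walking the ranked list from top to bottom, the running sum increases by
#' `n - k` at each of the k category members and decreases by `k` at each of
#' the n - k non-members, so it always returns to zero at the bottom. The
#' test statistic is the maximal absolute deviation from zero, D; a positive
#' maximum (mountain-like profile) means the category's genes accumulate at
#' the top of the list (enriched), a negative one (valley-like) at the
#' bottom (depleted).
#'
#' @param ranked Ranked-list tibble (`gene`, `score`), sorted by decreasing
#'   score.
#' @param members Character vector of category member ids (only those present
#'   in the ranked list count; at least one must be).
#' @return An object of class `trail_running_sum`: a list with elements
#'   `rs` (the n partial sums), `D`, `sign` (`"+"` if the first position
#'   attaining D is positive), `ambiguous` (TRUE when both +D and -D occur),
#'   `n`, `k`, and `positions` (member ranks).
#' @export
#' @examples
#' ranked <- tibble::tibble(gene = paste0("g", 1:6), score = 6:1)
#' running_sum(ranked, c("g1", "g2"))
running_sum <- function(ranked, members) {
  stopifnot(all(c("gene", "score") %in% names(ranked)))
  n <- nrow(ranked)
  hit <- ranked$gene %in% members
  k <- sum(hit)
  if (k == 0L) {
    stop("category has no members in the ranked list (k = 0)", call. = FALSE)
  }
  steps <- ifelse(hit, n - k, -k)
  rs <- cumsum(steps)
  D <- max(abs(rs))
  at_max <- which(abs(rs) == D)
  sign_at_max <- if (D == 0) "+" else if (rs[at_max[1]] > 0) "+" else "-"
  ambiguous <- D > 0 && length(unique(sign(rs[at_max]))) > 1L
  structure(
    list(
      rs = rs, D = D, sign = sign_at_max, ambiguous = ambiguous,
      n = n, k = k, positions = which(hit)
    ),
    class = "trail_running_sum"
  )
}

#' @export
print.trail_running_sum <- function(x, ...) {
  cat(sprintf(
    "Running sum: n = %d, k = %d, D = %s (%s)%s\n",
    x$n, x$k, format(x$D), if (x$sign == "+") "enriched" else "depleted",
    if (x$ambiguous) " [ambiguous sign]" else ""
  ))
  invisible(x)
}

#' Exact p-value for the running-sum statistic
#'
#' Probability, under uniform random placement of the k category members
#' among the n ranks, that the running sum reaches an absolute deviation of
#' at least `d` anywhere along the list. Computed by a dynamic program over
#' the lattice of states (position i, members used j): the survival
#' probability of never touching the region `|j*(n-k) - (i-j)*k| >= d` is
#' accumulated with sequential-sampling transition probabilities
#' `(k-j)/(n-i+1)`, and `p = 1 - survival`. Exact up to floating-point
#' rounding (well below 1e-12 for the sizes used here).
#'
#' @param n Ranked-list length (positive integer).
#' @param k Effective category size, `1 <= k <= n`.
#' @param d Observed maximal absolute deviation (non-negative integer on the
#'   running-sum scale).
#' @return The exact p-value. `d = 0` gives 1; `d > k*(n-k)` gives 0.
#' @export
#' @examples
#' gsea_exact_p(6, 2, 8) # 2/15: only placements {1,2} and {5,6} reach 8
gsea_exact_p <- function(n, k, d) {
  stopifnot(length(n) == 1L, length(k) == 1L, length(d) == 1L)
  if (n != round(n) || k != round(k) || d != round(d)) {
    stop("n, k and d must be integers", call. = FALSE)
  }
  if (k < 1 || k > n) stop("need 1 <= k <= n", call. = FALSE)
  if (d < 0) stop("d must be non-negative", call. = FALSE)
  if (d == 0) return(1)
  if (d > k * (n - k)) return(0)
  # state j = members used among first i ranks; RS_i = j*n - i*k
  surv <- c(1, rep(0, k))
  j <- 0:k
  for (i in seq_len(n)) {
    rem <- n - i + 1
    p_mem <- (k - j) / rem # P(rank i is a member | j used)
    new <- surv * (1 - p_mem)
    new[-1] <- new[-1] + (surv * p_mem)[-(k + 1)]
    new[abs(j * n - i * k) >= d] <- 0
    surv <- new
  }
  min(1, max(0, 1 - sum(surv)))
}

#' Monte-Carlo p-value for the running-sum statistic
#'
#' Permutation cross-check of [gsea_exact_p()]: places k members uniformly at
#' random `n_perm` times and reports
#' `(1 + #\{D* >= d_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams gsea_exact_p
#' @param d_obs Observed maximal absolute deviation.
#' @param n_perm Number of random placements (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return The add-one-smoothed permutation p-value.
#' @export
gsea_permutation_p <- function(n, k, d_obs, n_perm = 10000, seed = NULL) {
  stopifnot(n_perm >= 1, k >= 1, k <= n, d_obs >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (d_obs == 0) return(1)
  hits <- 0L
  steps0 <- rep(-k, n)
  for (b in seq_len(n_perm)) {
    steps <- steps0
    steps[sample.int(n, k)] <- n - k
    if (max(abs(cumsum(steps))) >= d_obs) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Unweighted GSEA over a category collection
#'
#' For every category with at least `min_size` members in the ranked list,
#' computes the running-sum statistic D and its p-value — exact by default,
#' falling back to the permutation estimate when the dynamic program would
#' exceed `max_dp_cells` lattice cells. Every category is evaluated against
#' the full list length n: genes belonging to no category still contribute
#' down-steps. Pass the result to [adjust_significance()] for FDR control.
#'
#' @param ranked Ranked-list tibble (`gene`, `score`), sorted.
#' @param categories Category tibble (`category`, `gene`), ideally already
#'   restricted to the ranked universe with [restrict_to_reference()].
#' @param min_size Minimum effective category size (default 2, the study's
#'   setting).
#' @param method `"exact"` (default) or `"permutation"`.
#' @param n_perm,seed Permutation settings, used only when the permutation
#'   path is taken.
#' @param max_dp_cells Cell budget above which the exact method falls back
#'   to permutation (default 5e7).
#' @return A `trail_gsea` tibble with one row per tested category: columns
#'   `category`, `k`, `n`, `D`, `direction` (`"enriched"`/`"depleted"`),
#'   `ambiguous`, `p_value`, `method`. Attributes record the ranked-list
#'   comparison label and the number of categories excluded by `min_size`.
#' @export
gsea_test <- function(ranked, categories, min_size = 2, method = c("exact", "permutation"),
                      n_perm = 10000, seed = NULL, max_dp_cells = 5e7) {
  method <- match.arg(method)
  check_categories(categories)
  stopifnot(all(c("gene", "score") %in% names(ranked)))
  n <- nrow(ranked)
  members <- dplyr::distinct(categories, .data$category, .data$gene) |>
    dplyr::filter(.data$gene %in% ranked$gene)
  sets <- split(members$gene, members$category)
  sizes <- lengths(sets)
  excluded <- names(sets)[sizes < min_size]
  sets <- sets[sizes >= min_size]
  rows <- purrr::imap(sets, function(mem, nm) {
    prof <- running_sum(ranked, mem)
    use_perm <- method == "permutation" ||
      (as.double(prof$n) * (prof$k + 1)) > max_dp_cells
    p <- if (use_perm) {
      gsea_permutation_p(prof$n, prof$k, prof$D, n_perm = n_perm, seed = seed)
    } else {
      gsea_exact_p(prof$n, prof$k, prof$D)
    }
    tibble::tibble(
      category = nm, k = prof$k, n = prof$n, D = prof$D,
      direction = if (prof$sign == "+") "enriched" else "depleted",
      ambiguous = prof$ambiguous, p_value = p,
      method = if (use_perm) "permutation" else "exact"
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      category = character(), k = integer(), n = integer(), D = numeric(),
      direction = character(), ambiguous = logical(), p_value = numeric(),
      method = character()
    )
  } else {
    out <- dplyr::arrange(out, .data$p_value, .data$category)
  }
  structure(out,
    class = c("trail_gsea", class(tibble::tibble())),
    comparison = attr(ranked, "comparison"),
    min_size = min_size, excluded = excluded, analysis = "gsea"
  )
}
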