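#' One-tailed hypergeometric tail probability
#'
#' With a reference universe of size `m` containing `k` category members,
#' drawing a test set of size `t` and observing `x` members in it: the upper
#' tail is `P(X >= x)` (over-representation), the lower tail `P(X <= x)`
#' (under-representation), for X hypergeometric. Computed with
#' [stats::phyper()]; exact.
#'
#' @param m Reference-set size.
#' @param k Category size within the reference.
#' @param t Test-set size, `t <= m`.
#' @param x Observed overlap, `0 <= x <= min(k, t)`.
#' @param direction `"upper"` or `"lower"`.
#' @return The one-tailed p-value.
#' @export
#' @examples
#' hypergeom_tail(10, 4, 5, 4, "upper") # 6/252
hypergeom_tail <- function(m, k, t, x, direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  if (any(c(m, k, t, x) != round(c(m, k, t, x)))) {
    stop("m, k, t, x must be integers", call. = FALSE)
  }
  if (k > m || t > m || x > min(k, t) || x < max(0, t - (m - k))) {
    stop("inconsistent counts: need x <= min(k, t), k <= m, t <= m, x >= t-(m-k)",
      call. = FALSE
    )
  }
  if (direction == "upper") {
    stats::phyper(x - 1, k, m - k, t, lower.tail = FALSE)
  } else {
    stats::phyper(x, k, m - k, t, lower.tail = TRUE)
  }
}

#' Over-representation analysis of a test set against a reference
#'
#' For each category, compares the observed overlap x of the test set with
#' the category against its expectation `e = t*k/m` under hypergeometric
#' sampling from the reference universe. Categories with `x >= e` are called
#' over-represented and tested with the upper tail, the rest
#' under-represented with the lower tail (the tie `x == e` yields an upper
#' tail of at least one half and is never significant). Test-set members
#' absent from the reference are dropped with a warning: the reference
#' defines the universe. Pass the result to [adjust_significance()] for FDR.
#'
#' @param test Character vector of selected gene ids (e.g. the union of
#'   differentially expressed genes).
#' @param reference Character vector: the gene universe (for the study's
#'   shape, all probe sets on the chip). See [read_reference()].
#' @param categories Category tibble; restricted to `reference` internally.
#' @param min_size Minimum category size within the reference (default 2).
#' @return A `trail_ora` tibble with one row per tested category: columns
#'   `category`, `m`, `k`, `t`, `x`, `expected`, `direction`
#'   (`"over-represented"`/`"under-represented"`), `p_value`.
#' @export
ora_test <- function(test, reference, categories, min_size = 2) {
  check_categories(categories)
  test <- unique(test)
  reference <- unique(as.character(reference))
  if (length(test) == 0L) stop("test set is empty", call. = FALSE)
  outside <- setdiff(test, reference)
  if (length(outside) > 0L) {
    warning(length(outside), " test-set member(s) absent from the reference were dropped",
      call. = FALSE
    )
    test <- intersect(test, reference)
    if (length(test) == 0L) {
      stop("no test-set members remain within the reference", call. = FALSE)
    }
  }
  m <- length(reference)
  t_n <- length(test)
  restricted <- suppressWarnings(restrict_to_reference(categories, reference))
  sets <- split(restricted$gene, restricted$category)
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) >= min_size]
  rows <- purrr::imap(sets, function(mem, nm) {
    k <- length(mem)
    x <- length(intersect(test, mem))
    e <- t_n * k / m
    dir <- if (x >= e) "over-represented" else "under-represented"
    p <- hypergeom_tail(m, k, t_n, x, if (x >= e) "upper" else "lower")
    tibble::tibble(
      category = nm, m = m, k = k, t = t_n, x = x, expected = e,
      direction = dir, p_value = p
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      category = character(), m = integer(), k = integer(), t = integer(),
      x = integer(), expected = numeric(), direction = character(),
      p_value = numeric()
    )
  } else {
    out <- dplyr::arrange(out, .data$p_value, .data$category)
  }
  structure(out,
    class = c("trail_ora", class(tibble::tibble())),
    min_size = min_size, analysis = "ora"
  )
}
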