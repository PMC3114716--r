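test_that("running sum reproduces the worked profiles and sign convention", {
  ranked <- make_ranked(paste0("g", 1:6))
  top <- running_sum(ranked, c("g1", "g2"))
  expect_equal(top$rs, c(4, 8, 6, 4, 2, 0))
  expect_equal(top$D, 8)
  expect_equal(top$sign, "+")

  bottom <- running_sum(ranked, c("g5", "g6"))
  expect_equal(bottom$rs, c(-2, -4, -6, -8, -4, 0))
  expect_equal(bottom$D, 8)
  expect_equal(bottom$sign, "-")

  # k = n: all increments are n - k = 0
  full <- running_sum(ranked, paste0("g", 1:6))
  expect_equal(full$rs, rep(0, 6))
  expect_equal(full$D, 0)

  expect_error(running_sum(ranked, "absent"), "k = 0")
})

test_that("running sum always returns to zero and flags ambiguous maxima", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    k <- sample(1:(n - 1), 1)
    prof <- running_sum(make_ranked(paste0("g", 1:n)), paste0("g", sample(n, k)))
    expect_equal(prof$rs[n], 0)
    expect_equal(prof$D, max(abs(prof$rs)))
    expect_lte(prof$D, k * (n - k))
  }
  # members at {1, 6} of n = 6: RS = 4,2,0,-2,-4,0 -> D attained only with -
  amb <- running_sum(make_ranked(paste0("g", 1:6)), c("g1", "g6"))
  expect_equal(amb$D, 4)
  expect_equal(amb$sign, "+") # first position attaining |4| is RS_1 = +4
  expect_true(amb$ambiguous)
})

test_that("exact p matches exhaustive enumeration for all n <= 12", {
  for (n in 2:12) {
    for (k in 1:n) {
      dvals <- oracle_d_values(n, k)
      for (d in sort(unique(dvals))) {
        expect_equal(gsea_exact_p(n, k, d), mean(dvals >= d),
          tolerance = 1e-12,
          label = sprintf("exact_p(%d, %d, %d)", n, k, d)
        )
      }
      # beyond the attainable maximum the tail is empty
      expect_equal(gsea_exact_p(n, k, k * (n - k) + 1), 0)
      expect_equal(gsea_exact_p(n, k, 0), 1)
    }
  }
})

test_that("exact p handles the worked case and validates inputs", {
  expect_equal(gsea_exact_p(6, 2, 8), 2 / 15, tolerance = 1e-12)
  expect_equal(gsea_exact_p(6, 2, 9), 0)
  expect_error(gsea_exact_p(6, 2.5, 3), "integers")
  expect_error(gsea_exact_p(6, 0, 3), "1 <= k <= n")
})

test_that("exact p is non-increasing in d and symmetric in list reversal", {
  for (n in c(8, 11)) {
    for (k in c(2, 4)) {
      p <- vapply(0:(k * (n - k)), function(d) gsea_exact_p(n, k, d), numeric(1))
      expect_false(is.unsorted(rev(p)))
    }
  }
  # reversing the ranked list preserves D and p and flips the direction
  ranked <- make_ranked(paste0("g", 1:9))
  rev_ranked <- make_ranked(paste0("g", 9:1))
  mem <- c("g1", "g2", "g4")
  a <- running_sum(ranked, mem)
  b <- running_sum(rev_ranked, mem)
  expect_equal(a$D, b$D)
  expect_equal(gsea_exact_p(9, 3, a$D), gsea_exact_p(9, 3, b$D))
  expect_true(a$sign != b$sign)
})

test_that("permutation p is reproducible and agrees with the exact value", {
  p1 <- gsea_permutation_p(6, 2, 8, n_perm = 5000, seed = 99)
  p2 <- gsea_permutation_p(6, 2, 8, n_perm = 5000, seed = 99)
  expect_identical(p1, p2)
  expect_equal(gsea_permutation_p(6, 2, 0, n_perm = 100, seed = 1), 1)

  p_exact <- 2 / 15
  p_hat <- gsea_permutation_p(6, 2, 8, n_perm = 20000, seed = 7)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(p_hat - p_exact), 3 * se)
})

test_that("gsea_test filters by size, reports symmetric disjoint categories", {
  ranked <- make_ranked(paste0("g", 1:6))
  cats <- tibble::tibble(
    category = c("top", "top", "bottom", "bottom", "tiny", "all")[c(1, 2, 3, 4, 5, rep(6, 6))],
    gene = c("g1", "g2", "g5", "g6", "g1", paste0("g", 1:6))
  )
  res <- gsea_test(ranked, cats, min_size = 2)
  expect_false("tiny" %in% res$category) # below the minimum size of two
  expect_true("tiny" %in% attr(res, "excluded"))

  top <- res[res$category == "top", ]
  bottom <- res[res$category == "bottom", ]
  expect_equal(top$p_value, 2 / 15)
  expect_equal(bottom$p_value, 2 / 15)
  expect_equal(top$direction, "enriched")
  expect_equal(bottom$direction, "depleted")

  all_row <- res[res$category == "all", ]
  expect_equal(all_row$D, 0)
  expect_equal(all_row$p_value, 1)
  expect_equal(unique(res$method), "exact")
})

test_that("gsea_test falls back to permutation beyond the DP cell budget", {
  ranked <- make_ranked(paste0("g", 1:30))
  cats <- tibble::tibble(category = "c", gene = c("g1", "g2", "g3"))
  res <- gsea_test(ranked, cats, max_dp_cells = 10, n_perm = 2000, seed = 5)
  expect_equal(res$method, "permutation")
  exact <- gsea_test(ranked, cats)
  expect_equal(res$p_value, exact$p_value, tolerance = 0.05)
})

test_that("raw GSEA p-values are conservative under the null", {
  # discrete statistic: P(p <= alpha) <= alpha for uniformly drawn categories
  set.seed(123)
  n <- 60
  ranked <- make_ranked(paste0("g", 1:n))
  alpha <- c(0.01, 0.05, 0.2)
  reps <- 400
  hits <- matrix(0, nrow = reps, ncol = length(alpha))
  for (r in seq_len(reps)) {
    k <- sample(3:8, 1)
    prof <- running_sum(ranked, paste0("g", sample(n, k)))
    p <- gsea_exact_p(n, k, prof$D)
    hits[r, ] <- p <= alpha
  }
  rate <- colMeans(hits)
  se <- sqrt(alpha * (1 - alpha) / reps)
  expect_true(all(rate <= alpha + 3 * se))
})
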