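test_that("smoothed variance reduces to the window mean and trims outliers", {
  st <- nia_settings(window_size = 100, trim_proportion = 0.01)
  # all variances equal: smoothing changes nothing
  v <- rep(2.5, 300)
  expect_equal(smoothed_variance(v, seq_along(v), st), v)

  # one huge variance among 99 equal ones is trimmed away inside its window
  v2 <- c(rep(1, 99), 1000)
  int2 <- seq_along(v2)
  sm <- smoothed_variance(v2, int2, nia_settings(window_size = 200, trim_proportion = 0.01))
  expect_equal(sm, rep(1, 100))

  # trim 0 gives the plain moving average
  v3 <- c(1, 2, 3, 4, 5)
  sm3 <- suppressWarnings(
    smoothed_variance(v3, 1:5, nia_settings(window_size = 2, trim_proportion = 0))
  )
  expect_equal(sm3, c(
    mean(v3[1:2]), mean(v3[1:3]), mean(v3[2:4]), mean(v3[3:5]), mean(v3[4:5])
  ))

  # values are returned in input gene order, not intensity order
  v4 <- c(10, 1, 1, 1)
  int4 <- c(4, 1, 2, 3) # gene 1 has the highest intensity
  sm4 <- smoothed_variance(v4, int4, nia_settings(window_size = 1, trim_proportion = 0))
  expect_equal(sm4, v4)

  expect_warning(
    smoothed_variance(rep(1, 10), 1:10, nia_settings(trim_proportion = 0.01)),
    "skipped"
  )
})

test_that("pairwise ANOVA: identical groups give F = 0 and p = 1", {
  ex <- tibble::tibble(
    gene = "g1", a1 = 1, a2 = 2, a3 = 3, b1 = 1, b2 = 2, b3 = 3
  )
  tab <- pairwise_anova(ex, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
    settings = nia_settings(log2_transform = FALSE, trim_proportion = 0)
  )
  expect_equal(tab$f_stat, 0)
  expect_equal(tab$p_value, 1)
  expect_equal(tab$df2, 4 + 10)
})

test_that("with no prior and the actual error model, F is the squared pooled t", {
  set.seed(5)
  ex <- dplyr::bind_cols(
    tibble::tibble(gene = paste0("g", 1:50)),
    tibble::as_tibble(as.data.frame(matrix(rlnorm(300, 3, 1), nrow = 50))) |>
      stats::setNames(c(paste0("a", 1:3), paste0("b", 1:3)))
  )
  st <- nia_settings(
    error_model = "actual", prior_df = 0, log2_transform = TRUE,
    window_size = 10, trim_proportion = 0
  )
  tab <- pairwise_anova(ex, paste0("a", 1:3), paste0("b", 1:3), settings = st)
  logm <- log2(as.matrix(ex[-1]) + 1)
  tstat <- vapply(seq_len(nrow(logm)), function(i) {
    t.test(logm[i, 1:3], logm[i, 4:6], var.equal = TRUE)$statistic
  }, numeric(1))
  expect_equal(tab$f_stat, tstat^2, tolerance = 1e-10)
  expect_equal(tab$p_value,
    pf(tstat^2, 1, 4, lower.tail = FALSE),
    tolerance = 1e-10
  )
})

test_that("a clean separation is significant even on a one-gene table", {
  ex <- tibble::tibble(
    gene = "g1", a1 = 0, a2 = 0, a3 = 0, b1 = 10, b2 = 10, b3 = 10
  )
  tab <- pairwise_anova(ex, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
    settings = nia_settings(log2_transform = FALSE, trim_proportion = 0)
  )
  expect_lt(tab$p_adj, 0.05)
  expect_true(tab$significant)
})

test_that("pairwise ANOVA is invariant to gene order and group swap", {
  set.seed(9)
  ex <- dplyr::bind_cols(
    tibble::tibble(gene = paste0("g", 1:30)),
    tibble::as_tibble(as.data.frame(matrix(rlnorm(180, 4, 0.5), nrow = 30))) |>
      stats::setNames(c(paste0("a", 1:3), paste0("b", 1:3)))
  )
  st0 <- nia_settings(trim_proportion = 0, window_size = 10)
  tab <- pairwise_anova(ex, paste0("a", 1:3), paste0("b", 1:3), settings = st0)
  shuf <- ex[sample(nrow(ex)), ]
  tab_shuf <- pairwise_anova(shuf, paste0("a", 1:3), paste0("b", 1:3), settings = st0)
  merged <- dplyr::inner_join(tibble::as_tibble(tab), tibble::as_tibble(tab_shuf),
    by = "gene", suffix = c("", ".s")
  )
  expect_equal(merged$p_value, merged$p_value.s, tolerance = 1e-12)

  swapped <- pairwise_anova(ex, paste0("b", 1:3), paste0("a", 1:3), settings = st0)
  expect_equal(tab$f_stat, swapped$f_stat, tolerance = 1e-12)
  expect_equal(tab$p_value, swapped$p_value, tolerance = 1e-12)

  expect_error(pairwise_anova(ex, "a1", paste0("b", 1:3)))
})

test_that("null simulations stay controlled and strong effects are recovered", {
  # complete null: 2000 genes, 3 vs 3 Gaussian noise
  set.seed(41)
  n_genes <- 2000
  m <- matrix(2^rnorm(n_genes * 6, 6, 0.5), nrow = n_genes)
  ex <- dplyr::bind_cols(
    tibble::tibble(gene = sprintf("g%04d", 1:n_genes)),
    stats::setNames(tibble::as_tibble(as.data.frame(m)), c(paste0("a", 1:3), paste0("b", 1:3)))
  )
  tab <- pairwise_anova(ex, paste0("a", 1:3), paste0("b", 1:3))
  expect_lte(sum(tab$significant), 5) # BH under the null: expectation near zero

  # effect 4 sigma in 20 of 200 genes: sensitivity >= 0.9
  set.seed(43)
  sigma <- 0.3
  base <- rnorm(200, 6, 1)
  de <- 1:20
  mu <- matrix(base, 200, 6)
  mu[de, 1:3] <- mu[de, 1:3] + 4 * sigma
  m2 <- 2^(mu + rnorm(200 * 6, 0, sigma))
  ex2 <- dplyr::bind_cols(
    tibble::tibble(gene = sprintf("g%03d", 1:200)),
    stats::setNames(tibble::as_tibble(as.data.frame(m2)), c(paste0("a", 1:3), paste0("b", 1:3)))
  )
  tab2 <- pairwise_anova(ex2, paste0("a", 1:3), paste0("b", 1:3))
  sens <- mean(tab2$significant[de])
  expect_gte(sens, 0.9)
})

test_that("the union selector pools significant genes once, split by tissue", {
  mk <- function(genes, sig, tissue, label) {
    tab <- tibble::tibble(
      gene = genes, significant = genes %in% sig
    )
    attr(tab, "tissue") <- tissue
    attr(tab, "comparison") <- label
    tab
  }
  tables <- list(
    mk(paste0("g", 1:5), c("g1", "g2"), "leaf", "A"),
    mk(paste0("g", 1:5), c("g2", "g3"), "leaf", "B"),
    mk(paste0("g", 1:5), "g4", "root", "C")
  )
  un <- select_de_union(tables)
  expect_setequal(un$gene, c("g1", "g2", "g3", "g4"))
  expect_equal(un$n_comparisons[un$gene == "g2"], 2L) # counted once, seen twice
  expect_equal(un$tissue[un$gene == "g2"], "leaf")
  expect_equal(un$tissue[un$gene == "g4"], "root")
  expect_equal(sum(un$tissue == "leaf"), 3L)
  expect_equal(sum(un$tissue == "root"), 1L)

  none <- select_de_union(list(mk(paste0("g", 1:3), character(), "leaf", "A")))
  expect_equal(nrow(none), 0L)
})
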