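# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: direct simulation of the running sum,
# exhaustive enumeration of member placements and of sampled subsets.

# Maximal |running sum| for members at `positions` in a list of length n,
# computed by direct simulation of the +(n-k)/-k walk.
oracle_max_dev <- function(n, positions) {
  k <- length(positions)
  steps <- rep(-k, n)
  steps[positions] <- n - k
  max(abs(cumsum(steps)))
}

# Exhaustive null distribution of D over all C(n, k) placements.
oracle_d_values <- function(n, k) {
  apply(utils::combn(n, k), 2, function(pos) oracle_max_dev(n, pos))
}

# Exact p by enumeration: fraction of placements with D >= d.
oracle_exact_p <- function(n, k, d) {
  mean(oracle_d_values(n, k) >= d)
}

# Hypergeometric tail by enumeration of all C(m, t) subsets of a universe
# containing k marked elements.
oracle_hyper_tail <- function(m, k, t, x, direction) {
  overlaps <- apply(utils::combn(m, t), 2, function(s) sum(s <= k))
  if (direction == "upper") mean(overlaps >= x) else mean(overlaps <= x)
}

# Hand step-up BH: q_(i) = min_{j >= i} m p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  out <- numeric(m)
  out[ord] <- pmin(1, q_sorted)
  out
}

# Quantile normalization by sort/row-mean/unsort with rank-tie averaging.
oracle_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    approx(seq_len(nrow(m)), target, xout = r)$y
  })
}

# A tiny ranked list with the given gene order (scores strictly decreasing).
make_ranked <- function(genes) {
  tibble::tibble(gene = genes, score = rev(seq_along(genes)))
}

# Small study-shaped simulated bundle shared by the pipeline tests.
small_bundle <- function(seed = 42, n_genes = 400, delta = 6,
                         comparisons = "root: WT -Fe vs WT +Fe",
                         n_decoys = 5) {
  cfg <- sim_config(
    n_genes = n_genes,
    implants = implant("implanted", 12, comparisons, delta = delta),
    n_decoys = n_decoys, decoy_size_range = c(8, 20)
  )
  simulate_experiment(cfg, seed = seed)
}
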