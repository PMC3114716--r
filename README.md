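# trailkit

Functional-category analysis of expression data: which biological gene sets
(pathway annotations, ontology terms, plant-physiology bins, or a custom
list such as a hand-curated metal-homeostasis category) move coherently
between two conditions, even when no single member gene passes a per-gene
significance cut?

`trailkit` implements the two classical answers and everything needed to
drive them over a factorial microarray-style design:

- **Unweighted GSEA with exact p-values.** Genes are ranked by fold change.
  Walking the list from top to bottom, a running sum RS increases by
  `n − k` at each of the `k` category members and decreases by `k`
  otherwise, so `RS_n = 0`. The statistic is the maximal absolute deviation
  `D = max_i |RS_i|`; a positive maximum ("mountain" profile) means
  enrichment at the top, a negative one ("valley") depletion. The p-value
  is `P(max_i |RS_i| ≥ D)` under uniform random placement of the `k`
  members among the `n` ranks, computed *exactly* by a dynamic program over
  the lattice of states (position, members used) — no asymptotics, no
  permutation noise (a seeded Monte-Carlo estimator is available as a
  cross-check and as a fallback for huge lists).
- **ORA.** A pre-selected test set of `t` genes (e.g. everything
  differentially expressed anywhere in the design) is compared against a
  reference universe of `m` genes containing `k` category members; the
  observed overlap `x` is tested against its expectation `e = t·k/m` with
  the one-tailed hypergeometric tail.
- **Significance calls** by Benjamini–Hochberg FDR at α = 0.05 (inclusive),
  one family per analysis run.
- **Preprocessing**: per-sample scaling to a target mean signal of 100,
  quantile normalization, replicate medians (n = 3 per condition by
  default), and log2 fold-change ranking with deterministic tie-breaking.
- **A regularized per-gene ANOVA selector** (3 vs 3 groups) whose error
  variance is the larger of the gene's own residual variance and an
  intensity-windowed trimmed average, shrunk with 10 prior degrees of
  freedom — the "max(average, actual)" style of error model used by
  microarray web tools.
- **Reporting** over the canonical eight pairwise comparisons of a
  2 tissue × 2 genotype × 2 treatment design: per-comparison
  induced/repressed count tables and disjoint Venn-region summaries of
  which categories are shared between comparisons.
- **A synthetic-data generator** that implants category-level effects with
  known ground truth, so the whole pipeline is testable offline.

Everything takes and returns tibbles and chains with the pipe; results have
`tidy()`/`glance()` methods and `autoplot()` views.

## Worked example

Simulate a study-shaped experiment (2 tissues × 2 genotypes × 2 Fe
treatments × 3 replicates) with a 15-gene "metal homeostasis" category
implanted at 3σ into the root iron-starvation contrast, plus 10 decoy
categories; then run the enrichment pipeline:

```r
library(trailkit)
library(dplyr)

cfg <- sim_config(
  n_genes = 1000,
  implants = implant("metal homeostasis", 15, "root: WT -Fe vs WT +Fe", delta = 3),
  n_decoys = 10
)
sim <- simulate_experiment(cfg, seed = 1)

medians <- sim$exprs |>
  scale_to_target() |>        # every sample mean -> 100
  quantile_normalize() |>     # all samples share one distribution
  replicate_median(sim$design)

ranked <- fold_change_ranking(medians, default_comparisons()[1, ])
res <- gsea_test(ranked, sim$categories) |> adjust_significance()
head(tidy(res), 4)
#> # A tibble: 4 × 11
#>   comparison category     k     n     D direction ambiguous p_value method p_adj
#>   <chr>      <chr>    <int> <int> <int> <chr>     <lgl>       <dbl> <chr>  <dbl>
#> 1 root: WT … metal h…    15  1000 14610 enriched  FALSE       0     exact  0
#> 2 root: WT … decoy003    15  1000  3460 depleted  FALSE       0.338 exact  0.957
#> 3 root: WT … decoy006    18  1000  3546 enriched  FALSE       0.419 exact  0.957
#> 4 root: WT … decoy008    34  1000  4716 enriched  FALSE       0.464 exact  0.957
```

The implanted category tops the table: its 15 members concentrate near the
head of the 1000-gene ranking, the running sum peaks at D = 14610, and the
exact p-value underflows to zero, while every decoy stays far from the
α = 0.05 line after FDR adjustment (`p_adj ≥ 0.96`).

Driving all eight comparisons and summarizing co-regulation:

```r
mat <- run_comparisons(medians, sim$categories)
venn_summary(mat)
#> # A tibble: 1 × 5
#>   category          region                       n_comparisons marks comparisons
#>   <chr>             <chr>                                <int> <chr> <list>
#> 1 metal homeostasis root: WT -Fe vs WT +Fe & ro…             2 root… <chr [2]>

head(count_table(mat), 4)
#> # A tibble: 4 × 4
#>   comparison                       induced repressed total
#>   <chr>                              <int>     <int> <int>
#> 1 root: WT -Fe vs WT +Fe                 1         0     1
#> 2 root: nas4x-1 -Fe vs nas4x-1 +Fe       0         0     0
#> 3 root: nas4x-1 +Fe vs WT +Fe            0         0     0
#> 4 root: nas4x-1 -Fe vs WT -Fe            0         1     1
```

The category lands in the Venn region shared by two comparisons — induced
in `WT -Fe vs +Fe` and repressed in `nas4x-1 -Fe vs WT -Fe`. The second
call is genuine, not leakage: a set of genes up-regulated in iron-starved
wild-type roots really is *relatively lower* in the mutant when both are
iron-starved, and the per-comparison `+`/`-` marks make that visible.

For a pre-selected gene list, `pairwise_anova()` /
`de_comparisons()` + `select_de_union()` produce the union of
differentially expressed genes across comparisons (partitioned by tissue),
and `ora_test(union$gene, sim$reference, sim$categories)` tests it against
the chip universe.

A thin command-line front end covering the same steps is installed as
`exec/trailkit` (subcommands `simulate`, `normalize`, `rank`, `gsea`,
`ora`, `diffexpr`, `compare`, `categories`).

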