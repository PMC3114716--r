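---
title: "Methods: enrichment statistics, preprocessing conventions, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment statistics, preprocessing conventions, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailkit)
```

This vignette is the package's account of the statistics it implements, the
conventions those statistics silently depend on, and the choices made where
the underlying methods are commonly described only informally. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The unweighted GSEA statistic

Given a list of $n$ genes ranked by some score (here: log2 fold change,
highest first) and a category with $k$ members on the list, the running sum
is

$$RS_i = \sum_{j \le i} s_j, \qquad
  s_j = \begin{cases} n - k & \text{gene } j \text{ in the category} \\
                      -k & \text{otherwise,} \end{cases}$$

so $RS_n = 0$ regardless of the placement. The statistic is the maximal
absolute deviation $D = \max_i |RS_i|$; the sign of $RS$ at the first
position attaining $D$ gives the direction (positive: members concentrate
at the top, the category is *enriched*; negative: *depleted*).

Conventions this package fixes, because the informal description
("increase on a member, decrease otherwise") does not:

- **Increment sizes $+(n-k)/-k$.** Any positive up/down pair gives the same
  *ranking* of placements, but this choice makes the walk return to zero,
  makes $D$ depend on the placement only (not on $n$ and $k$ separately
  through an offset), and makes the exact null computable by a clean
  dynamic program. It is the standard unweighted-GSEA convention.
- **Sign at the maximum.** When both $+D$ and $-D$ occur on one profile,
  the first position attaining $|D|$ decides the direction and the result
  row is flagged `ambiguous = TRUE`. Deterministic, and the flag keeps the
  corner case visible.
- **Ties in the ranking.** Tied fold changes are ordered lexicographically
  by gene identifier before the walk. The null distribution conditions on
  the ranking actually used, so tie handling must be deterministic;
  lexicographic order makes runs reproducible across machines.
- **Genes in no category still count.** Every category is evaluated
  against the full list length $n$; unannotated genes contribute $-k$
  steps. Excluding them would change $n$ per category and break
  comparability.

## The exact p-value

The p-value is the probability, under uniform random placement of the $k$
members among $n$ ranks, that any running sum reaches $\ge D$ in absolute
value. `gsea_exact_p()` computes the complementary survival probability by
dynamic programming over states $(i, j)$ = (ranks processed, members seen):
at rank $i$ the walk sits at $RS = jn - ik$, states with $|jn - ik| \ge D$
are absorbed, and transitions use the sequential-sampling probability
$(k-j)/(n-i+1)$ of the next rank being a member. This is algebraically the
lattice-path count divided by $\binom{n}{k}$, but carried out in
probabilities, so no big-integer arithmetic is needed; floating-point error
is at the $10^{-14}$ level, and the test suite pins the result against full
enumeration of all $\binom{n}{k}$ placements for every $n \le 12$.

The statistic is discrete, so the test is conservative:
$P(p \le \alpha) \le \alpha$ holds with slack, which the null-calibration
test and acceptance script measure directly (the realized rejection rate at
$\alpha = 0.05$ sits below 0.05).

Cost is $O(nk)$ cells. The exact path is the default up to a budget of
$5\times 10^7$ cells (`max_dp_cells`); beyond that `gsea_test()` falls back
to the seeded permutation estimator
$\hat p = (1 + \#\{D^* \ge D\})/(B+1)$, which is unbiased-conservative and
reproducible. For the list sizes this package targets (up to tens of
thousands of genes) the exact path is essentially always taken.

## ORA

With a reference universe of $m$ genes, $k$ of them in the category, and a
test set of $t$ genes overlapping the category in $x$, the expected overlap
is $e = tk/m$. If $x \ge e$ the category is called over-represented and
tested with the upper hypergeometric tail $P(X \ge x)$; otherwise
under-represented with $P(X \le x)$. Two deliberate conventions: the tie
$x = e$ goes to the over-represented branch (its upper tail is then at
least one half, so the choice can never manufacture significance), and
test-set members outside the reference are dropped with a warning rather
than enlarging $m$ — the reference defines the sampling universe, and
silently growing it would bias every category's expectation.

## FDR and significance

Both analyses hand their raw p-values to the Benjamini–Hochberg step-up
procedure (`stats::p.adjust`), one family per analysis run — per ranked
list for GSEA, per test set for ORA — matching how per-analysis result
pages are usually read. Pooling all eight comparisons into one family would
be more stringent and is available to the user by binding tidied tables and
adjusting once. The significance threshold $\alpha = 0.05$ on the adjusted
scale is inclusive ($\le$); the minimum category size default is 2.

## Preprocessing

- `scale_to_target()` multiplies each sample column by
  $\text{target}/\text{mean}$, with target 100 — the MAS-style global
  scaling convention for making arrays comparable.
- `quantile_normalize()` forces all samples onto the vector of row means of
  the column-sorted values (via `limma::normalizeQuantiles`, ties
  averaged). The transform is idempotent and rank-preserving within
  columns; tied raw values receive the mean of the quantile values they
  span.
- `replicate_median()` takes per-condition medians (designed for $n = 3$
  replicates, where the median discards exactly the extreme value).
- `fold_change_ranking()` scores $\log_2$ of the median ratio. A
  pseudocount defaults to 0 and a zero median is an error rather than a
  silent adjustment; pass a positive pseudocount explicitly when zeros are
  expected. Log2 versus plain ratios changes no ranking, and the ranking is
  all the enrichment statistic consumes.

## The ANOVA selector

Per gene, a single-factor two-group ANOVA on log2 signals with a
regularized error model in the style of the microarray web tools that
popularized "max(average, actual)" error handling. The published
description of those tools names the settings but not the formulas, so this
is a declared reconstruction with every knob exposed in `nia_settings()`:

1. residual variance $s^2_g$, pooled within groups,
   $\mathrm{df}_g = n_A + n_B - 2$;
2. a *smoothed* variance: genes ordered by mean log intensity, each gene
   averaging the residual variances in a centered window of 500 neighbours
   (clipped at the ends) after discarding the top 1% largest variances in
   the window — trimming stops a single outlier gene from inflating its
   whole neighbourhood, and is skipped with a warning when there are fewer
   genes than $1/\text{trim}$;
3. an error variance per the chosen model — `max_avg_actual` (default)
   takes $\max(s^2_{\text{smooth}}, s^2_g)$, so a gene is never granted
   *less* variance than it exhibited;
4. Bayesian shrinkage
   $s^2_{\text{post}} = (d_0 s^2_{\text{smooth}} + \mathrm{df}_g\,
   s^2_{\text{err}})/(d_0 + \mathrm{df}_g)$ with $d_0 = 10$ prior degrees
   of freedom;
5. $F = \mathrm{MS}_{\text{between}} / s^2_{\text{post}}$ with p from
   $F(1, \mathrm{df}_g + d_0)$, BH-adjusted across genes at 0.05.

"Zero mutations" in the conventional settings string is read as zero
permutations, i.e. parametric F p-values only. With $d_0 = 0$ and the
`actual` model the statistic reduces exactly to the squared pooled-variance
t, which the tests verify numerically. A small variance floor ($10^{-8}$)
keeps zero-variance genes finite. Log2 transform (offset 1) is on by
default and configurable off.

`select_de_union()` then pools genes significant in at least one
comparison, counted once, partitioned by the tissue of the comparisons that
flagged them — the shape needed to feed ORA with "everything differentially
expressed anywhere".

## Comparison driver and reporting

`default_comparisons()` expands the four biologically meaningful contrasts
per tissue — treatment within each genotype, genotype within each
treatment — over two tissues: eight comparisons. `run_comparisons()` ranks,
tests, and adjusts per comparison; a significant category enriched toward
the top of the test-vs-baseline ranking is *induced*, a depleted one
*repressed*. `venn_summary()` assigns each significant category to the
disjoint region given by the exact set of comparisons flagging it (regions
partition the categories; direction marks are per comparison, since a
category can be induced in one contrast and repressed in another), and
`count_table()` prints per-comparison induced/repressed/total counts, with
an optional category-to-area mapping for grouped counts. When a Venn over
many comparisons is unreadable the regions are still emitted; judging
whether a diagram is sensible is left to the user.

## Identifier mapping and reference restriction

Probe-to-gene relations on expression arrays are many-to-many.
`map_identifiers()` uses union semantics — a member maps to *all* its
images — because the reference universe is the chip: a gene's category
membership should reach every probe measuring it. Members without an image,
and categories emptied by mapping or by `restrict_to_reference()`, are
dropped and returned in a report rather than raising errors, since array
annotations are always incomplete. Category names are compared
case-sensitively after whitespace trimming. All downstream statistics use
the *restricted* category size $k$.

## The synthetic generator

`sim_config()` defaults encode the study-shaped conditions: 2000 genes,
2 tissues × 2 genotypes × 2 treatments, 3 replicates per condition,
baseline log2 signals $\mathcal N(6, 1.5)$ (raw signals on the order of
$2^6$, matching a target-100 scaling regime), replicate noise
$\sigma = 0.25$ on the log2 scale (a typical between-replicate spread for
well-behaved arrays), a per-gene tissue shift of sd 0.5 (structure between
tissues without touching any within-tissue contrast), and 20 decoy
categories of 10–40 genes sampled from non-implanted genes. Implants add
$\delta\sigma$ log2 units (multiplicative on the raw scale — matching what
fold-change ranking measures) to the *test condition* of each affected
comparison. Effect detectability therefore depends on $\delta$ only, not on
$\sigma$ itself.

Two honest limitations. First, the generator emulates clean, already
probe-summarized signals: no probe-level artifacts, saturation, batch
effects, or heavy-tailed noise — passing recovery tests shows the pipeline
recovers implanted structure under its own model, not that real arrays are
this kind. Second, factorial designs couple conditions: an effect placed in
the WT iron-starvation condition *is* a real difference in the
mutant-vs-WT-under-starvation contrast as well, so "implanted into
comparison A" does not imply "null everywhere else". Fixtures meant to be
significant in an exact set of comparisons use condition-cancelling pairs
(both `-Fe vs +Fe` contrasts), where the shifts subtract out of the
genotype contrasts.

## Problem sizes and tolerances

The test suite verifies the exact GSEA p against full enumeration for all
$n \le 12$, hypergeometric tails against subset enumeration for
$m \le 12$, null calibration over 1000 random rankings × 50 categories on a
50-gene list, recovery over 100 simulated experiments (2σ, 10-gene implant,
2000 genes, 20 decoys), and the ANOVA selector on a 10,000-gene null and a
200-gene 4σ power scenario; the acceptance script re-runs scaled versions
of the same computations (50 seeds for recovery, 500 rankings for
calibration) from a user-supplied seed. These sizes were chosen as the
smallest at which the binomial error of the measured rates is comfortably
below the margins being checked. Numerical tolerances: enumeration
agreement at $10^{-12}$, quantile-normalization round trips at $10^{-12}$,
BH bounds at $10^{-15}$ slack.
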