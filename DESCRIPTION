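Package: trailkit
Title: Gene Set Enrichment and Over-Representation Analysis with Exact
    Running-Sum P-Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unweighted gene set enrichment analysis (GSEA) with exact
    p-values computed by a lattice-path dynamic program over the running-sum
    statistic, over-representation analysis (ORA) with one-tailed
    hypergeometric p-values, Benjamini-Hochberg false discovery rate control,
    microarray-style preprocessing (target-signal scaling, quantile
    normalization, replicate medians, fold-change ranking), a regularized
    per-gene ANOVA selector for differential expression, and a reporting
    layer that drives factorial pairwise-comparison designs and summarizes
    significant functional categories as Venn regions and count tables.
    Includes a synthetic-data generator with implanted category-level
    enrichment so the whole pipeline can be exercised with known ground
    truth. All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    stats,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
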