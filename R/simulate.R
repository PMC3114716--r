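#' Configuration for a synthetic factorial microarray experiment
#'
#' Emulates the study-shaped design: a tissue x genotype x treatment grid
#' with three biological replicates per condition, log-normal baseline
#' signals, Gaussian replicate noise on the log2 scale, and category-level
#' effects implanted into chosen comparisons. Implanted categories receive
#' an additive shift of `delta * noise_sd` log2 units in the test condition
#' of each affected comparison (multiplicative on the raw scale, matching
#' fold-change ranking semantics). Decoy categories are sampled uniformly
#' from the non-implanted genes.
#'
#' @param n_genes Number of genes (default 2000).
#' @param tissues,genotypes,treatments Factor levels of the condition grid
#'   (defaults `c("root","leaf")`, `c("WT","nas4x-1")`, `c("+Fe","-Fe")`).
#' @param replicates Biological replicates per condition (default 3).
#' @param baseline_mean,baseline_sd Mean and sd of the per-gene baseline
#'   log2 signal (defaults 6 and 1.5).
#' @param noise_sd Replicate noise sd on the log2 scale (default 0.25).
#' @param tissue_effect_sd Sd of a per-gene tissue shift (default 0.5); adds
#'   between-tissue structure without touching any within-tissue comparison.
#' @param implants Tibble with one row per implanted category: columns
#'   `category`, `size`, `delta` (effect in units of `noise_sd`), `direction`
#'   (`"induced"`/`"repressed"`), and a list-column `comparisons` of affected
#'   comparison labels (must match `specs$comparison`).
#' @param n_decoys Number of decoy categories (default 20).
#' @param decoy_size_range Inclusive range decoy sizes are drawn from
#'   (default `c(10, 40)`).
#' @param specs Comparison tibble the implants refer to (default
#'   [default_comparisons()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       tissues = c("root", "leaf"),
                       genotypes = c("WT", "nas4x-1"),
                       treatments = c("+Fe", "-Fe"),
                       replicates = 3,
                       baseline_mean = 6, baseline_sd = 1.5,
                       noise_sd = 0.25, tissue_effect_sd = 0.5,
                       implants = NULL,
                       n_decoys = 20, decoy_size_range = c(10, 40),
                       specs = default_comparisons(tissues, genotypes, treatments)) {
  if (is.null(implants)) {
    implants <- tibble::tibble(
      category = character(), size = integer(), delta = numeric(),
      direction = character(), comparisons = list()
    )
  }
  stopifnot(
    n_genes >= 2, replicates >= 1, noise_sd > 0,
    all(c("category", "size", "delta", "direction", "comparisons") %in% names(implants))
  )
  if (nrow(implants) > 0L) {
    stopifnot(
      all(implants$size >= 2),
      all(implants$direction %in% c("induced", "repressed")),
      all(unlist(implants$comparisons) %in% specs$comparison)
    )
    if (sum(implants$size) > n_genes) {
      stop("implanted categories need more genes than n_genes", call. = FALSE)
    }
  }
  structure(
    list(
      n_genes = n_genes, tissues = tissues, genotypes = genotypes,
      treatments = treatments, replicates = replicates,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      noise_sd = noise_sd, tissue_effect_sd = tissue_effect_sd,
      implants = implants, n_decoys = n_decoys,
      decoy_size_range = decoy_size_range, specs = specs
    ),
    class = "sim_config"
  )
}

#' Shorthand for an implant table
#'
#' @param category Category name.
#' @param size Number of member genes.
#' @param comparisons Character vector of affected comparison labels.
#' @param delta Effect size in units of the replicate noise sd.
#' @param direction `"induced"` (members shifted up in the test condition)
#'   or `"repressed"`.
#' @return One implant row suitable for `sim_config(implants = ...)`; rows
#'   can be combined with [dplyr::bind_rows()].
#' @export
implant <- function(category, size, comparisons, delta = 2, direction = "induced") {
  tibble::tibble(
    category = category, size = as.integer(size), delta = delta,
    direction = direction, comparisons = list(comparisons)
  )
}

#' Simulate an expression experiment with known category-level truth
#'
#' Draws per-gene baseline log2 signals, adds a per-gene tissue shift and
#' i.i.d. Gaussian replicate noise, implants the configured category effects
#' into the test conditions of their affected comparisons, and exponentiates
#' to the raw signal scale. Member genes of the implanted categories are
#' disjoint across implants and from the decoys' sampling pool.
#'
#' @param cfg A [sim_config()] object.
#' @param seed Integer seed; the same seed yields a bitwise-identical
#'   result.
#' @return A list with elements `exprs` (expression tibble), `design`
#'   (sample design tibble), `categories` (implanted + decoy category
#'   tibble), `reference` (all simulated gene ids), and `truth` (a list with
#'   the implant table and the per-gene, per-comparison true effects
#'   tibble).
#' @export
simulate_experiment <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  conditions <- tidyr::expand_grid(
    tissue = cfg$tissues, genotype = cfg$genotypes, treatment = cfg$treatments
  )
  design <- tidyr::expand_grid(conditions, replicate = seq_len(cfg$replicates)) |>
    dplyr::mutate(sample = sprintf(
      "%s_%s_%s_r%d", .data$tissue, .data$genotype,
      gsub("[^A-Za-z0-9]", "", chartr("+-", "pm", .data$treatment)), .data$replicate
    )) |>
    dplyr::select("sample", "tissue", "genotype", "treatment", "replicate")

  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  tissue_shift <- matrix(
    stats::rnorm(cfg$n_genes * length(cfg$tissues), 0, cfg$tissue_effect_sd),
    nrow = cfg$n_genes,
    dimnames = list(genes, cfg$tissues)
  )

  # assign implant members first (disjoint), decoys from the remainder
  implants <- cfg$implants
  pool <- genes
  member_sets <- list()
  if (nrow(implants) > 0L) {
    for (i in seq_len(nrow(implants))) {
      mem <- pool[seq_len(implants$size[i])]
      pool <- setdiff(pool, mem)
      member_sets[[implants$category[i]]] <- mem
    }
  }
  decoy_sets <- list()
  if (cfg$n_decoys > 0L) {
    sizes <- sample(cfg$decoy_size_range[1]:cfg$decoy_size_range[2],
      cfg$n_decoys,
      replace = TRUE
    )
    for (i in seq_len(cfg$n_decoys)) {
      decoy_sets[[sprintf("decoy%03d", i)]] <- sample(pool, sizes[i])
    }
  }
  categories <- dplyr::bind_rows(
    purrr::imap_dfr(member_sets, ~ tibble::tibble(
      category = .y, gene = .x, source = "implant"
    )),
    purrr::imap_dfr(decoy_sets, ~ tibble::tibble(
      category = .y, gene = .x, source = "decoy"
    ))
  )
  if (nrow(categories) == 0L) {
    categories <- tibble::tibble(
      category = character(), gene = character(), source = character()
    )
  }
  categories <- new_categories(categories, "gene")

  # per-(gene, condition) effect from the implants
  effect <- matrix(0,
    nrow = cfg$n_genes, ncol = nrow(conditions),
    dimnames = list(genes, NULL)
  )
  cond_key <- with(conditions, paste(tissue, genotype, treatment))
  truth_rows <- list()
  if (nrow(implants) > 0L) {
    for (i in seq_len(nrow(implants))) {
      mem <- member_sets[[implants$category[i]]]
      sgn <- if (implants$direction[i] == "induced") 1 else -1
      shift <- sgn * implants$delta[i] * cfg$noise_sd
      for (cmp in implants$comparisons[[i]]) {
        spec <- cfg$specs[cfg$specs$comparison == cmp, ]
        target <- paste(spec$tissue, spec$test_genotype, spec$test_treatment)
        effect[mem, cond_key == target] <-
          effect[mem, cond_key == target] + shift
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          gene = mem, comparison = cmp,
          category = implants$category[i],
          direction = implants$direction[i],
          log2_effect = shift
        )
      }
    }
  }
  truth_genes <- if (length(truth_rows)) {
    dplyr::bind_rows(truth_rows)
  } else {
    tibble::tibble(
      gene = character(), comparison = character(), category = character(),
      direction = character(), log2_effect = numeric()
    )
  }

  values <- matrix(NA_real_, nrow = cfg$n_genes, ncol = nrow(design))
  for (s in seq_len(nrow(design))) {
    ci <- which(cond_key == paste(design$tissue[s], design$genotype[s], design$treatment[s]))
    mu <- baseline + tissue_shift[, design$tissue[s]] + effect[, ci]
    values[, s] <- 2^(mu + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd))
  }
  exprs <- tibble::as_tibble(
    stats::setNames(as.data.frame(values), design$sample)
  )
  exprs <- dplyr::bind_cols(tibble::tibble(gene = genes), exprs)

  list(
    exprs = exprs, design = design, categories = categories,
    reference = structure(genes, namespace = "gene", label = "simulated"),
    truth = list(implants = implants, genes = truth_genes, seed = seed)
  )
}

#' Write a simulated bundle as plain-text fixture files
#'
#' Emits exactly the formats the pipeline consumes: `matrix.tsv`,
#' `design.tsv`, `categories.gmt`, `reference.txt`, and `truth.json`
#' (implant table with member genes, serialized with sorted keys so the
#' bytes are deterministic given the seed).
#'
#' @param bundle Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(all(c("exprs", "design", "categories", "reference", "truth") %in% names(bundle)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "matrix.tsv"),
    design = file.path(dir, "design.tsv"),
    categories = file.path(dir, "categories.gmt"),
    reference = file.path(dir, "reference.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_exprs(bundle$exprs, paths["matrix"])
  write_design(bundle$design, paths["design"])
  write_gmt(bundle$categories, paths["categories"])
  writeLines(sort(unique(as.character(bundle$reference))), paths["reference"])
  truth <- list(
    seed = bundle$truth$seed,
    implants = lapply(seq_len(nrow(bundle$truth$implants)), function(i) {
      row <- bundle$truth$implants[i, ]
      mem <- sort(unique(
        bundle$truth$genes$gene[bundle$truth$genes$category == row$category]
      ))
      list(
        category = row$category, size = row$size, delta = row$delta,
        direction = row$direction,
        comparisons = sort(row$comparisons[[1]]),
        members = mem
      )
    })
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
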