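#' Read and write pipeline tables
#'
#' Plain-text TSV readers/writers for the formats the pipeline consumes and
#' emits: expression matrices (header = sample names, first column = gene
#' id), design tables, and sorted ranked lists (the two-column upload format
#' for enrichment analysis).
#'
#' @param path File path.
#' @return `read_exprs()` an expression tibble; `read_design()` a design
#'   tibble; `read_ranked_list()` a ranked-list tibble sorted by decreasing
#'   score.
#' @name trailkit-io
NULL

#' @rdname trailkit-io
#' @export
read_exprs <- function(path) {
  x <- readr::read_tsv(path,
    col_types = readr::cols(
      gene = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  names(x)[1] <- "gene"
  check_exprs(x)
  x
}

#' @rdname trailkit-io
#' @param exprs Expression tibble.
#' @export
write_exprs <- function(exprs, path) {
  check_exprs(exprs)
  readr::write_tsv(exprs, path, progress = FALSE)
  invisible(path)
}

#' @rdname trailkit-io
#' @export
read_design <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
}

#' @rdname trailkit-io
#' @param design Design tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' @rdname trailkit-io
#' @export
read_ranked_list <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c("gene", "score"),
    col_types = readr::cols(
      gene = readr::col_character(),
      score = readr::col_double()
    ),
    progress = FALSE
  )
  dplyr::arrange(x, dplyr::desc(.data$score), .data$gene)
}

#' @rdname trailkit-io
#' @param ranked Ranked-list tibble (`gene`, `score`), as produced by
#'   [fold_change_ranking()].
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(all(c("gene", "score") %in% names(ranked)))
  readr::write_tsv(ranked[c("gene", "score")], path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}
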