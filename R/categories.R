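#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set dialect: one set per line with fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate member tokens
#' within a line are collapsed (set semantics); category names are trimmed of
#' surrounding whitespace and compared case-sensitively.
#'
#' @param path Path to a GMT file.
#' @param namespace Identifier kind the members are expressed in, e.g.
#'   `"gene"` (AGI locus codes) or `"probe"` (array probe-set IDs). Stored as
#'   the `namespace` attribute and checked by downstream operations.
#' @return A tibble with one row per (category, gene) pair and columns
#'   `category`, `gene`, `source` (the GMT description field). The
#'   `namespace` attribute records `namespace`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("metal\tcustom\tNAS1\tNAS2", f)
#' read_gmt(f)
read_gmt <- function(path, namespace = "gene") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(new_categories(
      tibble::tibble(category = character(), gene = character(), source = character()),
      namespace
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields",
      call. = FALSE
    )
  }
  names <- trimws(vapply(fields, `[[`, character(1), 1L))
  if (anyDuplicated(names)) {
    stop("duplicate category name in GMT: ",
      paste(unique(names[duplicated(names)]), collapse = ", "),
      call. = FALSE
    )
  }
  out <- purrr::map2_dfr(fields, names, function(f, nm) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    tibble::tibble(category = nm, gene = members, source = f[[2]])
  })
  new_categories(out, namespace)
}

#' Write a category table to a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, f))` gives back an equal
#' table (up to row order, which is normalized to category then gene).
#'
#' @param categories A category tibble (`category`, `gene`, optional `source`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(categories, path) {
  check_categories(categories)
  split <- dplyr::group_by(categories, .data$category)
  lines <- dplyr::group_map(split, function(rows, key) {
    src <- if ("source" %in% names(rows)) rows$source[[1]] else "custom"
    paste(c(key$category, src, sort(unique(rows$gene))), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a two-column gene-to-category table
#'
#' The long format used for MapMan bin assignments and custom lists: each
#' non-comment line is `gene<TAB>category`. A gene may appear under several
#' categories. Lines starting with `#` are skipped.
#'
#' @inheritParams read_gmt
#' @param source Source label stored in the `source` column (default
#'   `"custom"`).
#' @return A category tibble as in [read_gmt()].
#' @export
read_gene2cat <- function(path, namespace = "gene", source = "custom") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(new_categories(
      tibble::tibble(category = character(), gene = character(), source = character()),
      namespace
    ))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad) > 0L) {
    stop("malformed line ", idx[bad[1]], ": expected 'gene<TAB>category'",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    category = trimws(vapply(fields, `[[`, character(1), 2L)),
    gene = vapply(fields, `[[`, character(1), 1L),
    source = source
  ) |>
    dplyr::distinct(.data$category, .data$gene, .keep_all = TRUE) |>
    dplyr::arrange(.data$category, .data$gene)
  new_categories(out, namespace)
}

#' Read an identifier map (probe-set ID to gene code)
#'
#' Two-column TSV relating identifiers in two namespaces, e.g. ATH1 probe-set
#' IDs to AGI locus codes. Many-to-many pairs are allowed; exact duplicate
#' pairs are collapsed.
#'
#' @param path Path to a two-column TSV (`from<TAB>to`, `#` comments allowed).
#' @param from,to Namespace labels for the two columns.
#' @return A tibble with columns named after `from` and `to`.
#' @export
read_id_map <- function(path, from = "probe", to = "gene") {
  stopifnot(file.exists(path))
  x <- readr::read_tsv(path,
    col_names = c(from, to), comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (any(!nzchar(x[[from]])) || any(!nzchar(x[[to]])) ||
    anyNA(x[[from]]) || anyNA(x[[to]])) {
    stop("identifier map contains empty fields", call. = FALSE)
  }
  dplyr::distinct(x)
}

#' Read a reference set (one identifier per line)
#'
#' @param path Path to a text file with one identifier per line (`#` comments
#'   and blank lines skipped).
#' @param namespace Identifier kind, as in [read_gmt()].
#' @return A character vector of unique identifiers with attributes
#'   `namespace` and `label`.
#' @export
read_reference <- function(path, namespace = "gene") {
  stopifnot(file.exists(path))
  x <- trimws(readLines(path, warn = FALSE))
  x <- unique(x[nzchar(x) & !startsWith(x, "#")])
  if (length(x) == 0L) stop("reference set is empty", call. = FALSE)
  structure(x, namespace = namespace, label = basename(path))
}

#' Translate category members between identifier namespaces
#'
#' Replaces each member by all of its images under the map (union semantics
#' for one-to-many relations, so a gene's category membership propagates to
#' every probe that measures it). Members with no image are dropped and
#' reported; categories left empty are removed and reported.
#'
#' @param categories A category tibble.
#' @param idmap An identifier map from [read_id_map()] (or any two-column
#'   data frame).
#' @param to Name of the `idmap` column to translate into; the other column
#'   must match the table's current namespace attribute if one is set.
#' @return The translated category tibble, with `namespace` set to `to` and a
#'   `dropped` attribute (tibble of `category`, `gene` pairs that had no
#'   image, plus rows with `gene = NA` for categories removed outright);
#'   retrieve it with [dropped_report()].
#' @export
map_identifiers <- function(categories, idmap, to) {
  check_categories(categories)
  stopifnot(is.data.frame(idmap), to %in% names(idmap), ncol(idmap) >= 2L)
  from <- setdiff(names(idmap), to)[[1]]
  ns <- attr(categories, "namespace")
  if (!is.null(ns) && identical(ns, to)) {
    stop("collection is already in namespace '", to, "'", call. = FALSE)
  }
  map <- dplyr::distinct(idmap[, c(from, to)])
  names(map) <- c(".from", ".to")
  joined <- dplyr::left_join(
    dplyr::rename(categories, .member = "gene"), map,
    by = c(.member = ".from"), relationship = "many-to-many"
  )
  dropped <- joined |>
    dplyr::filter(is.na(.data$.to)) |>
    dplyr::distinct(category = .data$category, gene = .data$.member)
  out <- joined |>
    dplyr::filter(!is.na(.data$.to)) |>
    dplyr::mutate(gene = .data$.to) |>
    dplyr::select(-".to", -".member") |>
    dplyr::distinct(.data$category, .data$gene, .keep_all = TRUE) |>
    dplyr::arrange(.data$category, .data$gene)
  lost_cats <- setdiff(unique(categories$category), unique(out$category))
  if (length(lost_cats) > 0L) {
    dropped <- dplyr::bind_rows(
      dropped,
      tibble::tibble(category = lost_cats, gene = NA_character_)
    )
  }
  res <- new_categories(out, to)
  attr(res, "dropped") <- dropped
  res
}

#' Restrict categories to a reference set
#'
#' Intersects every category with the reference universe (for the study's
#' shape: all probe sets present on the chip). The member counts of the
#' returned table are the effective category sizes `k` used by all downstream
#' statistics. Idempotent; empty intersections are removed and reported.
#'
#' @param categories A category tibble.
#' @param reference Character vector of identifiers (see [read_reference()]).
#' @return The restricted category tibble with a `dropped` attribute listing
#'   removed categories (`gene = NA`) and out-of-reference members.
#' @export
restrict_to_reference <- function(categories, reference) {
  check_categories(categories)
  ns_c <- attr(categories, "namespace")
  ns_r <- attr(reference, "namespace")
  if (!is.null(ns_c) && !is.null(ns_r) && !identical(ns_c, ns_r)) {
    stop("namespace mismatch: categories are '", ns_c,
      "' but reference is '", ns_r, "'",
      call. = FALSE
    )
  }
  keep <- categories$gene %in% reference
  dropped <- dplyr::distinct(categories[!keep, c("category", "gene")])
  out <- categories[keep, , drop = FALSE]
  lost <- setdiff(unique(categories$category), unique(out$category))
  if (length(lost) > 0L) {
    dropped <- dplyr::bind_rows(
      dropped, tibble::tibble(category = lost, gene = NA_character_)
    )
  }
  res <- new_categories(tibble::as_tibble(out), ns_c %||% ns_r)
  attr(res, "dropped") <- dropped
  res
}

#' Retrieve the dropped-identifier report attached by a mapping or
#' restriction step
#'
#' @param categories A category tibble returned by [map_identifiers()] or
#'   [restrict_to_reference()].
#' @return A tibble of dropped (`category`, `gene`) pairs; rows with
#'   `gene = NA` mark whole categories that became empty and were removed.
#' @export
dropped_report <- function(categories) {
  attr(categories, "dropped") %||%
    tibble::tibble(category = character(), gene = character())
}

#' Sizes of each category
#'
#' @param categories A category tibble.
#' @return A tibble with columns `category` and `k` (number of distinct
#'   members).
#' @export
category_sizes <- function(categories) {
  check_categories(categories)
  dplyr::count(
    dplyr::distinct(categories, .data$category, .data$gene),
    .data$category,
    name = "k"
  )
}

new_categories <- function(df, namespace) {
  stopifnot(all(c("category", "gene") %in% names(df)))
  attr(df, "namespace") <- namespace
  df
}

check_categories <- function(x) {
  if (!is.data.frame(x) || !all(c("category", "gene") %in% names(x))) {
    stop("expected a category table with columns 'category' and 'gene'",
      call. = FALSE
    )
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
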