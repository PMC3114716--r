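test_that("GMT parsing splits fields, de-duplicates members, and round-trips", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "metal\tcustom\tNAS1\tNAS2",
    "dup\td\tg1\tg1",
    "big\tGO\tg1\tg2\tg3"
  ), f)
  coll <- read_gmt(f, namespace = "gene")
  expect_equal(sum(coll$category == "metal"), 2L)
  expect_equal(coll$gene[coll$category == "metal"], c("NAS1", "NAS2"))
  expect_equal(sum(coll$category == "dup"), 1L) # set semantics
  expect_equal(attr(coll, "namespace"), "gene")
  expect_equal(coll$source[coll$category == "big"][1], "GO")

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, out)
  reparsed <- read_gmt(out, namespace = "gene")
  expect_equal(
    dplyr::arrange(tibble::as_tibble(coll), category, gene),
    dplyr::arrange(tibble::as_tibble(reparsed), category, gene)
  )
})

test_that("GMT parsing rejects malformed lines and duplicate names, allows empty files", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ok\td\tg1", "short\tonly2fields"), f)
  expect_error(read_gmt(f), "line 2")

  writeLines(c("a\td\tg1", "a\td\tg2"), f)
  expect_error(read_gmt(f), "duplicate")

  writeLines(character(), f)
  expect_equal(nrow(read_gmt(f)), 0L)
})

test_that("two-column gene-to-category parsing groups by category", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "g1\tcatA", "g2\tcatA", "g1\tcatB"), f)
  coll <- read_gene2cat(f)
  expect_equal(coll$gene[coll$category == "catA"], c("g1", "g2"))
  expect_equal(coll$gene[coll$category == "catB"], "g1")

  # a single bin holding 47 distinct genes yields one category of size 47
  writeLines(sprintf("AT%02dG\ttransport.metal", 1:47), f)
  sizes <- category_sizes(read_gene2cat(f))
  expect_equal(sizes$k, 47L)

  writeLines("bad line with no tab", f)
  expect_error(read_gene2cat(f), "line 1")

  writeLines(character(), f)
  expect_equal(nrow(read_gene2cat(f)), 0L)
})

test_that("identifier mapping uses union semantics and reports drops", {
  coll <- tibble::tibble(
    category = c("c1", "c1", "c2"),
    gene = c("g1", "g2", "g3")
  )
  coll <- trailkit:::new_categories(coll, "gene")
  idmap <- tibble::tibble(
    gene = c("g1", "g1", "g3"),
    probe = c("p1", "p2", "p3")
  )
  mapped <- map_identifiers(coll, idmap, to = "probe")
  expect_setequal(mapped$gene[mapped$category == "c1"], c("p1", "p2"))
  expect_equal(mapped$gene[mapped$category == "c2"], "p3")
  expect_equal(attr(mapped, "namespace"), "probe")
  rep <- dropped_report(mapped)
  expect_equal(rep$gene[rep$category == "c1"], "g2")

  # identity map leaves the collection unchanged
  ident <- tibble::tibble(gene = c("g1", "g2", "g3"), probe = c("g1", "g2", "g3"))
  same <- map_identifiers(coll, ident, to = "probe")
  expect_equal(
    dplyr::arrange(tibble::as_tibble(same)[c("category", "gene")], category, gene),
    dplyr::arrange(tibble::as_tibble(coll)[c("category", "gene")], category, gene),
    ignore_attr = TRUE
  )

  # a category with no mapped members is removed and recorded
  lost <- map_identifiers(coll, tibble::tibble(gene = "g1", probe = "p1"), to = "probe")
  expect_false("c2" %in% lost$category)
  expect_true("c2" %in% dropped_report(lost)$category)
})

test_that("round-trip through the inverse map never increases category count", {
  coll <- trailkit:::new_categories(
    tibble::tibble(
      category = rep(c("a", "b", "c"), times = c(3, 2, 1)),
      gene = c("g1", "g2", "g3", "g2", "g4", "g5")
    ), "gene"
  )
  idmap <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"),
    probe = c("p1", "p2", "p3", "p2")
  )
  there <- map_identifiers(coll, idmap, to = "probe")
  back <- map_identifiers(there, idmap, to = "gene")
  expect_lte(dplyr::n_distinct(back$category), dplyr::n_distinct(coll$category))
})

test_that("reference restriction intersects, removes empties, and is idempotent", {
  coll <- trailkit:::new_categories(
    tibble::tibble(
      category = c("x", "x", "x", "y", "z"),
      gene = c("a", "b", "c", "b", "q")
    ), "gene"
  )
  ref <- structure(c("b", "c", "d"), namespace = "gene")
  res <- restrict_to_reference(coll, ref)
  expect_setequal(res$gene[res$category == "x"], c("b", "c"))
  expect_equal(category_sizes(res)$k[category_sizes(res)$category == "x"], 2L)
  expect_false("z" %in% res$category) # disjoint category removed
  expect_true("z" %in% dropped_report(res)$category)

  twice <- restrict_to_reference(res, ref)
  expect_equal(
    tibble::as_tibble(twice)[c("category", "gene")],
    tibble::as_tibble(res)[c("category", "gene")],
    ignore_attr = TRUE
  )
  expect_equal(nrow(dropped_report(twice)), 0L)

  expect_error(
    restrict_to_reference(coll, structure("p1", namespace = "probe")),
    "namespace"
  )
})

test_that("reference and id-map readers validate their inputs", {
  f <- withr::local_tempfile()
  writeLines(c("# header", "g1", "g2", "", "g1"), f)
  ref <- read_reference(f)
  expect_setequal(as.character(ref), c("g1", "g2"))

  writeLines(character(), f)
  expect_error(read_reference(f), "empty")

  writeLines(c("p1\tg1", "p1\tg1", "p2\tg2"), f)
  m <- read_id_map(f)
  expect_equal(nrow(m), 2L) # exact duplicate pair collapsed
  expect_named(m, c("probe", "gene"))
})
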