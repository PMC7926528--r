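test_that("reading a source collapses duplicates and normalizes identifiers", {
  df <- tibble::tibble(
    mirna = c("hsa-mir-21", "hsa-miR-21", "miR-9"),
    gene = c("Msx2", "MSX2", "VDR")
  )
  cat1 <- read_target_source(df, "pairs", source_tag = "ts")
  expect_equal(nrow(cat1), 2L)
  expect_equal(sort(unique(cat1$mirna)), c("hsa-miR-21", "hsa-miR-9"))
  expect_true(all(cat1$sources == "ts"))

  expect_error(read_target_source(df, list(mirna_col = "mir", gene_col = "gene"),
                                  source_tag = "x"),
               "mir")
  expect_warning(
    empty <- read_target_source(df[0, ], "pairs", source_tag = "x"),
    "zero parsed pairs"
  )
  expect_equal(nrow(empty), 0L)
})

test_that("custom dialects read files with arbitrary column names", {
  path <- write_lines_tmp(c("mir\ttarget\tctx",
                            "miR-1\tGJA1\t-0.2",
                            "miR-1\tgja1\t-0.1"))
  cat1 <- read_target_source(
    path, list(mirna_col = "mir", gene_col = "target", score_col = "ctx"),
    source_tag = "targetscan"
  )
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$gene, "GJA1")
})

test_that("combination policies implement set algebra over sources", {
  s1 <- toy_catalog(data.frame(mirna = c("m1", "m1"), gene = c("GA", "GB")), "s1")
  s2 <- toy_catalog(data.frame(mirna = "m1", gene = "GB"), "s2")

  u <- combine_catalogs(list(s1, s2), "union")
  i <- combine_catalogs(list(s1, s2), "intersection")
  v <- combine_catalogs(list(s1, s2), "min_sources", k = 2)
  expect_equal(nrow(u), 2L)
  expect_equal(nrow(i), 1L)
  expect_equal(i$gene, "GB")
  expect_equal(v$gene, "GB")
  expect_equal(i$sources, "s1;s2")

  single <- combine_catalogs(list(s1), "intersection")
  expect_equal(single[c("mirna", "gene")], s1[c("mirna", "gene")])
  expect_error(combine_catalogs(list(s1, s2), "min_sources", k = 3), "k exceeds")
})

test_that("policy nesting and order invariance hold on random catalogs", {
  for (seed in 1:5) {
    cats <- random_catalog(seed)
    u <- combine_catalogs(cats, "union")
    i <- combine_catalogs(cats, "intersection")
    v <- combine_catalogs(cats, "min_sources", k = 2)
    key <- function(x) paste(x$mirna, x$gene)
    expect_true(all(key(i) %in% key(v)))
    expect_true(all(key(v) %in% key(u)))
    perm <- combine_catalogs(rev(cats), "union")
    expect_equal(u[c("mirna", "gene", "sources")],
                 perm[c("mirna", "gene", "sources")])
  }
})

test_that("per-gene miRNA counts include the zero class", {
  cat1 <- toy_catalog(data.frame(
    mirna = c("m1", "m2", "m1"), gene = c("GA", "GA", "GB")
  ))
  counts <- mirna_counts_per_gene(cat1, c("GA", "GB", "GC"))
  expect_equal(counts$n_mirnas[match(c("GA", "GB", "GC"), counts$gene)],
               c(2L, 1L, 0L))
  expect_equal(attr(counts, "zero_genes"), "GC")
  expect_equal(genes_above_mirna_threshold(counts, 1), "GA")
  # sum of counts equals distinct pairs restricted to the set
  expect_equal(sum(counts$n_mirnas), 3L)

  empty <- suppressWarnings(
    toy_catalog(data.frame(mirna = character(), gene = character()))
  )
  counts0 <- mirna_counts_per_gene(empty, "GA")
  expect_equal(counts0$n_mirnas, 0L)
  expect_error(mirna_counts_per_gene(cat1, character()), "empty")
})

test_that("universe restriction drops outside pairs and records the universe", {
  cat1 <- toy_catalog(data.frame(mirna = c("m1", "m2"), gene = c("GA", "GB")))
  same <- restrict_to_universe(cat1, c("GA", "GB"))
  expect_equal(nrow(same), 2L)
  expect_equal(catalog_universe(same), c("GA", "GB"))

  cut <- restrict_to_universe(cat1, "GA")
  expect_equal(cut$gene, "GA")
  expect_warning(none <- restrict_to_universe(cat1, "GZ"), "empty")
  expect_equal(nrow(none), 0L)
  expect_error(restrict_to_universe(cat1, character()), "universe is empty")
})

test_that("catalog TSV round trip is stable", {
  cat1 <- toy_catalog(data.frame(mirna = c("m2", "m1"), gene = c("GB", "GA")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat1, path)
  back <- read_catalog(path)
  expect_equal(back[c("mirna", "gene", "sources")],
               cat1[c("mirna", "gene", "sources")])
  write_catalog(back, path2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_identical(readLines(path), readLines(path2))
})
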