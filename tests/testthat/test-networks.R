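toy_results <- function() {
  cfg <- test_config(universe_size = 1000, set_size = 10)
  cat1 <- toy_catalog(data.frame(
    mirna = c("m1", "m1", "m2", "m3", "m3", "m3"),
    gene = c("GA", "GB", "GA", "GC", "GD", "GX")
  ))
  enrich(cat1, c("GA", "GB", "GC", "GD"), cfg)
}

test_that("bipartite network mirrors the enrichment overlap structure", {
  res <- toy_results()
  net <- build_bipartite(res, significant_only = FALSE)
  expect_equal(igraph::ecount(net), sum(res$k_overlap))
  modes <- igraph::V(net)$mode
  expect_setequal(unique(modes), c("mirna", "gene"))
  # no within-mode edge
  el <- igraph::as_edgelist(net)
  m <- stats::setNames(modes, igraph::V(net)$name)
  expect_true(all(m[el[, 1]] != m[el[, 2]]))

  single <- build_bipartite(res[res$mirna == "m1", ], significant_only = FALSE)
  expect_equal(igraph::vcount(single), 3L)
  expect_equal(igraph::ecount(single), 2L)

  empty <- build_bipartite(res[0, ], significant_only = FALSE)
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("PPI merge canonicalizes, deduplicates, and drops self-loops", {
  f1 <- write_lines_tmp(c("A\tB", "B\tC"))
  f2 <- write_lines_tmp(c("B\tA", "C\tC"))
  expect_message(net <- merge_ppi(list(f1, f2)), "self-loop")
  expect_equal(igraph::ecount(net), 2L)
  ab <- igraph::E(net)$sources[[1]]
  expect_true(grepl(";", ab)) # both provenances on the A-B edge

  # merging a file with itself is idempotent
  once <- merge_ppi(list(f1))
  twice <- merge_ppi(list(f1, f1))
  expect_equal(igraph::as_edgelist(once), igraph::as_edgelist(twice))
  # degree-sum identity
  expect_equal(sum(igraph::degree(net)), 2L * igraph::ecount(net))
})

test_that("PSI-MITAB records map identifiers through gene-name aliases", {
  mitab <- write_lines_tmp(c(
    paste("uniprotkb:P11473", "uniprotkb:Q13950", "-", "-",
          "uniprotkb:VDR(gene name)|uniprotkb:NR1I1(gene name synonym)",
          "uniprotkb:RUNX2(gene name)", "psi-mi:MI(0018)", sep = "\t"),
    paste("uniprotkb:P11473", "uniprotkb:P17302", "-", "-",
          "uniprotkb:VDR(gene name)", "-", "psi-mi", sep = "\t"),
    "badline"
  ), ext = ".mitab")
  expect_message(tbl <- read_interactions(mitab, "intact"), "line")
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$a, c("VDR", "VDR"))
  expect_equal(tbl$b[1], "RUNX2")
  expect_equal(tbl$b[2], "P17302") # no alias: raw identifier kept

  none <- write_lines_tmp("# comment only")
  expect_warning(empty <- read_interactions(none, "x"), "no valid")
  expect_equal(nrow(empty), 0L)
})

test_that("seed degree ranking counts interactors with stated tie-breaks", {
  star <- merge_ppi(list(data.frame(
    a = rep("SEED", 5), b = paste0("I", 1:5)
  )))
  rank <- seed_degree_ranking(star, c("SEED", "ZABSENT"))
  expect_equal(rank$seed[1], "SEED")
  expect_equal(rank$degree[1], 5L)
  expect_equal(rank$degree[rank$seed == "ZABSENT"], 0L)
  expect_equal(rank$seed[nrow(rank)], "ZABSENT")

  tie <- merge_ppi(list(data.frame(a = c("B", "A"), b = c("X", "X"))))
  r2 <- seed_degree_ranking(tie, c("B", "A"))
  expect_equal(r2$seed, c("A", "B")) # equal degree: alphabetical
  expect_error(seed_degree_ranking(star, character()), "empty")
})

test_that("neighborhood subgraph keeps seeds plus first neighbors only", {
  chain <- merge_ppi(list(data.frame(a = c("A", "B"), b = c("B", "C"))))
  sub <- neighbor_subgraph(chain, "A")
  expect_setequal(igraph::V(sub)$name, c("A", "B"))
  expect_equal(igraph::ecount(sub), 1L)
  expect_equal(igraph::V(sub)$role[igraph::V(sub)$name == "A"], "seed")

  all_seeds <- neighbor_subgraph(chain, c("A", "B", "C"))
  expect_equal(igraph::ecount(all_seeds), igraph::ecount(chain))

  lonely <- neighbor_subgraph(chain, "ZZ")
  expect_equal(igraph::V(lonely)$name, "ZZ")
  expect_equal(igraph::ecount(lonely), 0L)
})

test_that("network exports are deterministic and round-trip", {
  res <- toy_results()
  bip <- build_bipartite(res, significant_only = FALSE)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(bip, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, sum(res$k_overlap))
  expect_true(all(grepl("\ttargets\t", lines)))
  expect_false(is.unsorted(lines))
  # miRNA endpoint first on every line
  expect_true(all(startsWith(lines, "m")))

  sif2 <- withr::local_tempfile(fileext = ".sif")
  write_network(bip, sif2, "sif")
  expect_identical(readLines(sif), readLines(sif2))

  ppi <- merge_ppi(list(data.frame(a = c("A", "B"), b = c("B", "C"))))
  psif <- withr::local_tempfile(fileext = ".sif")
  write_network(ppi, psif, "sif")
  expect_true(all(grepl("\tpp\t", readLines(psif))))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(bip, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(bip))
  expect_equal(igraph::ecount(back), igraph::ecount(bip))

  empty <- build_bipartite(res[0, ], significant_only = FALSE)
  esif <- withr::local_tempfile(fileext = ".sif")
  write_network(empty, esif, "sif")
  expect_length(readLines(esif), 0L)
})
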