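# md5 digests of the packaged fixture files; guards against silent corruption
.fixture_md5 <- c(
  ai_table1_isolated_syndromic.tsv = "b3b233c8e1f7786327cb0ce0972b9e00",
  ai_table2_inheritance.tsv        = "2c8d5fb24d73f697aaf2a59695c86483",
  ai_table3_phenotype.tsv          = "6ade6de6a3a27766f91cc51977632655",
  ai_table4_mirna.tsv              = "6f60fcc6d3383f0805fd1a4af465adf6"
)

ai_extdata <- function(file) {
  path <- system.file("extdata", file, package = "aimirna", mustWork = TRUE)
  digest <- unname(tools::md5sum(path))
  if (!identical(digest, unname(.fixture_md5[[file]]))) {
    rlang::abort(paste0("checksum mismatch on packaged fixture '", file, "'"))
  }
  path
}

#' Packaged curated classification tables
#'
#' The three classification tables of the curated amelogenesis imperfecta
#' gene registry, shipped verbatim (including the source's spelling variants,
#' which the alias map corrects at load): the isolated/syndromic table, the
#' inheritance table, and the enamel phenotype table.
#'
#' @return Named list of three tibbles (`isolated_syndromic`, `inheritance`,
#'   `phenotype`), each with columns `category` and `genes`.
#' @export
ai_tables <- function() {
  read1 <- function(file) {
    readr::read_tsv(ai_extdata(file),
                    col_types = readr::cols(.default = "c"), progress = FALSE)
  }
  list(
    isolated_syndromic = read1("ai_table1_isolated_syndromic.tsv"),
    inheritance = read1("ai_table2_inheritance.tsv"),
    phenotype = read1("ai_table3_phenotype.tsv")
  )
}

#' The curated 56-gene amelogenesis imperfecta registry
#'
#' Loads the packaged classification tables into a normalized registry; see
#' [load_registry()].
#'
#' @return An `ai_registry` tibble of 56 records.
#' @export
#' @examples
#' nrow(ai_registry())
ai_registry <- function() {
  tabs <- ai_tables()
  load_registry(tabs$isolated_syndromic, tabs$inheritance, tabs$phenotype,
                provenance = "curated amelogenesis imperfecta registry")
}

#' The packaged 37-row miRNA enrichment table
#'
#' The published per-miRNA screen results: for each significant miRNA its
#' overlap genes within the disease set, its total target count, the overlap
#' count, and the printed exact-test p-value.
#'
#' @return Tibble with columns `mirna`, `overlap_genes` (list-column of
#'   sorted symbols), `n_targets`, `k_overlap`, `p_value`.
#' @export
#' @examples
#' nrow(ai_table4())
ai_table4 <- function() {
  tbl <- readr::read_tsv(
    ai_extdata("ai_table4_mirna.tsv"),
    col_types = readr::cols(
      mirna = "c", overlap_genes = "c",
      n_targets = "i", k_overlap = "i", p_value = "d"
    ),
    progress = FALSE
  )
  tbl$overlap_genes <- lapply(tbl$overlap_genes, function(cell)
    sort(normalize_symbols(split_gene_list(cell))))
  tbl
}

#' Load all packaged fixtures
#'
#' @return List with `registry` (the 56-gene `ai_registry`) and `table4`
#'   (the 37-row enrichment table, see [ai_table4()]).
#' @export
load_fixtures <- function() {
  list(registry = ai_registry(), table4 = ai_table4())
}

#' Reconstruct a target catalog from printed enrichment rows
#'
#' Builds a catalog in which each miRNA has exactly its printed number of
#' targets, of which the printed overlap genes lie in the disease set and the
#' remainder are synthetic background symbols outside it. Running [enrich()]
#' on this catalog with the background recovered by [invert_background()]
#' reproduces the printed screen.
#'
#' @param rows Tibble like [ai_table4()]: `mirna`, `overlap_genes`
#'   (list-column), `n_targets`, `k_overlap`.
#' @param gene_set Character vector of disease gene symbols; background
#'   filler symbols are guaranteed to avoid it.
#' @return An `ai_catalog`.
#' @export
reconstruct_catalog <- function(rows, gene_set) {
  rows <- tibble::as_tibble(rows)
  n_fill <- rows$n_targets - rows$k_overlap
  if (any(n_fill < 0)) {
    rlang::abort("k_overlap exceeds n_targets")
  }
  filler_pool <- sprintf("BGGENE%05d", seq_len(max(n_fill, 0L)))
  stopifnot(!any(filler_pool %in% gene_set))
  pairs <- purrr::pmap_dfr(
    rows[c("mirna", "overlap_genes", "n_targets", "k_overlap")],
    function(mirna, overlap_genes, n_targets, k_overlap) {
      tibble::tibble(
        mirna = mirna,
        gene = c(sort(unique(overlap_genes)),
                 filler_pool[seq_len(n_targets - k_overlap)]),
        sources = "printed_table"
      )
    }
  )
  new_catalog(pairs)
}
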