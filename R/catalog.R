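#' Normalize miRNA identifiers
#'
#' Trims whitespace and canonicalizes the species/`miR` prefix to the
#' `hsa-miR-...` form regardless of input case or separator (`hsa_mir_21`,
#' `miR-21`, `MIR21` all become `hsa-miR-21`). Arm suffixes (`-5p`/`-3p`) are
#' preserved verbatim; no attempt is made to merge arms.
#'
#' @param x Character vector of miRNA identifiers.
#' @return Canonicalized identifiers.
#' @export
#' @examples
#' normalize_mirna(c("hsa-mir-3195", "miR-382-5p"))
normalize_mirna <- function(x) {
  x <- trimws(as.character(x))
  sub("^(hsa[-_]?)?mir[-_]?", "hsa-miR-", x, ignore.case = TRUE)
}

# bundled column-mapping presets for prediction-source TSV dialects
.dialect_presets <- list(
  pairs  = list(mirna_col = "mirna", gene_col = "gene", score_col = NULL),
  scored = list(mirna_col = "mirna", gene_col = "gene", score_col = "score")
)

resolve_dialect <- function(dialect) {
  if (is.character(dialect) && length(dialect) == 1L) {
    if (!dialect %in% names(.dialect_presets)) {
      rlang::abort(paste0("unknown dialect preset '", dialect, "'"))
    }
    return(.dialect_presets[[dialect]])
  }
  dialect <- as.list(dialect)
  if (is.null(dialect$mirna_col) || is.null(dialect$gene_col)) {
    rlang::abort("dialect must name 'mirna_col' and 'gene_col'")
  }
  if (is.null(dialect$score_col)) dialect["score_col"] <- list(NULL)
  dialect
}

new_catalog <- function(pairs, universe = NULL) {
  pairs <- dplyr::arrange(tibble::as_tibble(pairs), .data$mirna, .data$gene)
  attr(pairs, "universe") <- universe
  class(pairs) <- unique(c("ai_catalog", class(pairs)))
  pairs
}

#' The gene universe attached to a target catalog
#'
#' When no explicit universe has been set, defaults to all genes observed in
#' the catalog, so that the enrichment background is always well defined.
#'
#' @param catalog An `ai_catalog` tibble.
#' @return Character vector of gene symbols.
#' @export
catalog_universe <- function(catalog) {
  u <- attr(catalog, "universe")
  if (is.null(u)) sort(unique(catalog$gene)) else sort(unique(u))
}

#' Read one miRNA-target prediction source
#'
#' Parses a tabular prediction export (TargetScan/miRanda/PITA/miRTarBase-like
#' TSV) into a single-source catalog. The dialect names which columns hold the
#' miRNA identifier, the gene symbol, and optionally a prediction score; two
#' presets are bundled: `"pairs"` (`mirna`, `gene`) and `"scored"` (`mirna`,
#' `gene`, `score`). Duplicate rows collapse to one pair; identifiers are
#' normalized via [normalize_mirna()] and [normalize_symbols()]. Scores are
#' carried but ignored by enrichment, which uses presence/absence only.
#'
#' @param file Path to a TSV with a header row, or a data frame.
#' @param dialect Preset name or named list with `mirna_col`, `gene_col`,
#'   optionally `score_col`.
#' @param source_tag Provenance tag recorded on every pair.
#' @param aliases Alias map for gene-symbol normalization.
#' @return An `ai_catalog` tibble with columns `mirna`, `gene`, `sources`, and
#'   `score` (NA when the dialect has no score column).
#' @export
read_target_source <- function(file, dialect = "pairs", source_tag,
                               aliases = ai_alias_map()) {
  d <- resolve_dialect(dialect)
  tbl <- if (is.data.frame(file)) {
    tibble::as_tibble(file)
  } else {
    readr::read_tsv(file, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  miss <- setdiff(c(d$mirna_col, d$gene_col, d$score_col), names(tbl))
  if (length(miss)) {
    rlang::abort(paste0("missing mapped column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(tbl) == 0L) {
    rlang::warn(paste0("zero parsed pairs in source '", source_tag, "'"))
    return(new_catalog(tibble::tibble(
      mirna = character(), gene = character(),
      sources = character(), score = numeric()
    )))
  }
  out <- tibble::tibble(
    mirna = normalize_mirna(tbl[[d$mirna_col]]),
    gene = normalize_symbols(tbl[[d$gene_col]], aliases),
    sources = source_tag,
    score = if (is.null(d$score_col)) NA_real_ else as.numeric(tbl[[d$score_col]])
  ) |>
    dplyr::group_by(.data$mirna, .data$gene, .data$sources) |>
    dplyr::summarise(score = .data$score[1], .groups = "drop")
  new_catalog(out)
}

#' Combine target catalogs under an explicit policy
#'
#' The curated analysis pools several prediction algorithms without stating a
#' combination rule; the rule is therefore an explicit knob. `union` keeps any
#' pair reported by any source (the default), `intersection` keeps pairs
#' present in every input catalog, and `min_sources` keeps pairs backed by at
#' least `k` distinct source tags. Provenance is merged in all cases.
#'
#' @param catalogs List of `ai_catalog` objects.
#' @param policy `"union"`, `"intersection"`, or `"min_sources"`.
#' @param k Minimum number of distinct source tags for `min_sources`.
#' @return A combined `ai_catalog`.
#' @export
combine_catalogs <- function(catalogs, policy = c("union", "intersection",
                                                  "min_sources"), k = 2L) {
  policy <- match.arg(policy)
  if (length(catalogs) < 1L) {
    rlang::abort("need at least one catalog")
  }
  if (policy == "min_sources" && k > length(catalogs)) {
    rlang::abort("k exceeds the number of catalogs")
  }
  long <- purrr::imap_dfr(catalogs, function(cat, i) {
    dplyr::mutate(tibble::as_tibble(cat)[c("mirna", "gene", "sources")],
                  .catalog = i)
  }) |>
    tidyr::separate_rows("sources", sep = ";")

  merged <- long |>
    dplyr::group_by(.data$mirna, .data$gene) |>
    dplyr::summarise(
      n_catalogs = dplyr::n_distinct(.data$.catalog),
      n_sources = dplyr::n_distinct(.data$sources),
      sources = paste(sort(unique(.data$sources)), collapse = ";"),
      .groups = "drop"
    )
  keep <- switch(policy,
    union = rep(TRUE, nrow(merged)),
    intersection = merged$n_catalogs == length(catalogs),
    min_sources = merged$n_sources >= k
  )
  universes <- purrr::compact(lapply(catalogs, attr, "universe"))
  new_catalog(
    merged[keep, c("mirna", "gene", "sources")],
    universe = if (length(universes)) sort(unique(unlist(universes))) else NULL
  )
}

#' Count distinct miRNAs targeting each gene of a set
#'
#' Genes of the set absent from the catalog get count 0; these form the
#' "not yet reported as associated with miRNAs" class, retrievable from the
#' `zero_genes` attribute.
#'
#' @param catalog An `ai_catalog`.
#' @param gene_set Character vector of normalized gene symbols.
#' @return Tibble with columns `gene`, `n_mirnas`, sorted by descending count
#'   then symbol; attribute `zero_genes` lists the count-0 genes.
#' @export
mirna_counts_per_gene <- function(catalog, gene_set) {
  gene_set <- sort(unique(gene_set))
  if (length(gene_set) == 0L) {
    rlang::abort("gene set is empty")
  }
  counts <- tibble::as_tibble(catalog) |>
    dplyr::filter(.data$gene %in% gene_set) |>
    dplyr::distinct(.data$mirna, .data$gene) |>
    dplyr::count(.data$gene, name = "n_mirnas")
  out <- tibble::tibble(gene = gene_set) |>
    dplyr::left_join(counts, by = "gene") |>
    dplyr::mutate(n_mirnas = as.integer(tidyr::replace_na(.data$n_mirnas, 0L))) |>
    dplyr::arrange(dplyr::desc(.data$n_mirnas), .data$gene)
  attr(out, "zero_genes") <- out$gene[out$n_mirnas == 0L]
  out
}

#' Genes targeted by more than a threshold number of miRNAs
#'
#' @param counts Output of [mirna_counts_per_gene()].
#' @param min_mirnas Threshold; genes with strictly more miRNAs are returned.
#' @return Sorted character vector of gene symbols.
#' @export
genes_above_mirna_threshold <- function(counts, min_mirnas) {
  sort(counts$gene[counts$n_mirnas > min_mirnas])
}

#' Restrict a catalog to an explicit gene universe
#'
#' Drops pairs whose gene lies outside the universe and records the universe
#' on the catalog, making the enrichment background explicit.
#'
#' @param catalog An `ai_catalog`.
#' @param universe Non-empty character vector of gene symbols.
#' @return Restricted `ai_catalog` with its `universe` attribute set.
#' @export
restrict_to_universe <- function(catalog, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) {
    rlang::abort("universe is empty")
  }
  kept <- dplyr::filter(tibble::as_tibble(catalog), .data$gene %in% universe)
  if (nrow(kept) == 0L && nrow(catalog) > 0L) {
    rlang::warn("no catalog gene lies in the universe; catalog is now empty")
  }
  new_catalog(kept, universe = universe)
}

#' Read / write a combined catalog as TSV
#'
#' Columns `mirna`, `gene`, `sources` (semicolon-delimited), sorted by
#' (mirna, gene) for diff-stable files.
#'
#' @param path File path.
#' @return `read_catalog()` returns an `ai_catalog`.
#' @export
read_catalog <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("mirna", "gene", "sources") %in% names(tbl))) {
    rlang::abort("catalog TSV needs columns mirna, gene, sources")
  }
  new_catalog(tbl[c("mirna", "gene", "sources")])
}

#' @rdname read_catalog
#' @param catalog An `ai_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  out <- dplyr::arrange(tibble::as_tibble(catalog)[c("mirna", "gene", "sources")],
                        .data$mirna, .data$gene)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
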