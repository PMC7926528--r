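#' Build the miRNA-gene bipartite regulation network
#'
#' One miRNA node per retained enrichment result, one gene node per distinct
#' overlap gene, and one edge per (miRNA, overlap gene) pair -- the two-mode
#' regulation network laid over the enrichment screen.
#'
#' @param results An `ai_enrichment` tibble from [enrich()].
#' @param significant_only Keep only rows passing the significance filter.
#' @return An undirected `igraph` with vertex attributes `mode`
#'   (`"mirna"`/`"gene"`) and `type` (`TRUE` for genes; the igraph bipartite
#'   convention).
#' @export
build_bipartite <- function(results, significant_only = TRUE) {
  res <- tibble::as_tibble(results)
  if (significant_only && "significant" %in% names(res)) {
    res <- dplyr::filter(res, .data$significant)
  }
  edges <- res |>
    dplyr::select("mirna", "overlap_genes") |>
    tidyr::unnest("overlap_genes") |>
    dplyr::distinct(.data$mirna, gene = .data$overlap_genes)
  mirnas <- sort(unique(res$mirna))
  genes <- sort(unique(edges$gene))
  nodes <- tibble::tibble(
    name = c(mirnas, genes),
    mode = rep(c("mirna", "gene"), c(length(mirnas), length(genes))),
    type = rep(c(FALSE, TRUE), c(length(mirnas), length(genes)))
  )
  igraph::graph_from_data_frame(
    dplyr::arrange(edges, .data$mirna, .data$gene),
    directed = FALSE, vertices = nodes
  )
}

# strip a "db:" prefix from a PSI-MITAB identifier field
strip_db_prefix <- function(x) {
  sub("^[^:]+:", "", x)
}

# prefer a "(gene name)"-tagged alias from a MITAB alias field, else the raw id
mitab_symbol <- function(id, alias) {
  pick_alias <- function(a) {
    if (is.na(a) || a == "-" || !nzchar(a)) return(NA_character_)
    parts <- strsplit(a, "|", fixed = TRUE)[[1]]
    named <- parts[grepl("\\(gene name\\)$", parts)]
    if (length(named) == 0L) return(NA_character_)
    sub("\\(gene name\\)$", "", strip_db_prefix(named[1]))
  }
  out <- vapply(alias, pick_alias, character(1), USE.NAMES = FALSE)
  ifelse(is.na(out), strip_db_prefix(id), out)
}

#' Read an interaction file (PSI-MITAB 2.5 or 2-column edge list)
#'
#' Files with at least six tab-delimited columns are treated as PSI-MITAB:
#' columns 1-2 are the interactor identifiers and columns 5-6 their alias
#' fields, from which a `(gene name)`-tagged alias is preferred over the raw
#' identifier (no online identifier resolution). Narrower files are read as
#' 2-column TSV edge lists. Lines starting with `#` and unparseable lines
#' (fewer than two fields) are skipped, the latter with a logged line number.
#'
#' @param file File path.
#' @param source_tag Provenance tag; defaults to the file name.
#' @return Tibble with columns `a`, `b`, `sources`.
#' @export
read_interactions <- function(file, source_tag = NULL) {
  if (is.null(source_tag)) {
    source_tag <- sub("\\.[^.]*$", "", basename(file))
  }
  lines <- readLines(file)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 2L
  if (any(bad)) {
    message("skipping unparseable line(s): ",
            paste(line_no[bad], collapse = ", "))
    fields <- fields[!bad]
  }
  if (length(fields) == 0L) {
    rlang::warn(paste0("no valid interaction records in '", file, "'"))
    return(tibble::tibble(a = character(), b = character(),
                          sources = character()))
  }
  wide <- lengths(fields) >= 6L
  get <- function(f, i) if (length(f) >= i) f[[i]] else NA_character_
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  a5 <- vapply(fields, get, character(1), 5L)
  b6 <- vapply(fields, get, character(1), 6L)
  tibble::tibble(
    a = ifelse(wide, mitab_symbol(a, a5), a),
    b = ifelse(wide, mitab_symbol(b, b6), b),
    sources = source_tag
  )
}

#' Merge interaction sources into one undirected PPI network
#'
#' Pairs are canonicalized (lexicographic endpoint order) so that `A-B` and
#' `B-A` collapse to a single edge; duplicates across sources merge with
#' provenance union; self-loops are dropped with a logged count. The merge is
#' commutative and idempotent over its source list.
#'
#' @param sources List of interaction inputs: file paths (read with
#'   [read_interactions()]) or data frames with columns `a`, `b` and
#'   optionally `sources`.
#' @return An undirected `igraph` with edge attribute `sources`
#'   (semicolon-delimited) and vertex attribute `role` (all `"interactor"`
#'   until seeds are flagged by [neighbor_subgraph()]).
#' @export
merge_ppi <- function(sources) {
  if (!is.list(sources) || is.data.frame(sources)) sources <- list(sources)
  long <- purrr::imap_dfr(sources, function(s, i) {
    tbl <- if (is.data.frame(s)) tibble::as_tibble(s) else read_interactions(s)
    if (!"sources" %in% names(tbl)) tbl$sources <- paste0("source", i)
    tbl[c("a", "b", "sources")]
  })
  loops <- long$a == long$b
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    long <- long[!loops, ]
  }
  edges <- long |>
    dplyr::mutate(from = pmin(.data$a, .data$b),
                  to = pmax(.data$a, .data$b)) |>
    tidyr::separate_rows("sources", sep = ";") |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      sources = paste(sort(unique(.data$sources)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$from, .data$to)
  nodes <- tibble::tibble(name = sort(unique(c(edges$from, edges$to))),
                          role = "interactor")
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Degree ranking of disease seed genes in a merged PPI network
#'
#' The degree of a seed is its number of distinct interactors in the merged
#' network; seeds absent from the network get degree 0. Sorted by descending
#' degree, ties broken alphabetically.
#'
#' @param ppi An `igraph` from [merge_ppi()].
#' @param seeds Non-empty character vector of seed gene symbols.
#' @return Tibble with columns `seed`, `degree`, sorted.
#' @export
seed_degree_ranking <- function(ppi, seeds) {
  seeds <- unique(seeds)
  if (length(seeds) == 0L) {
    rlang::abort("seed set is empty")
  }
  present <- intersect(seeds, igraph::V(ppi)$name)
  deg <- stats::setNames(rep(0L, length(seeds)), seeds)
  if (length(present)) {
    deg[present] <- as.integer(igraph::degree(ppi, v = present))
  }
  tibble::tibble(seed = names(deg), degree = unname(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$seed)
}

#' First-neighborhood subgraph around disease seed genes
#'
#' Induced subgraph on the seeds plus their first neighbors. Seeds missing
#' from the network are added as isolated nodes so the seed set is always
#' fully represented. Vertex attribute `role` flags `"seed"` versus
#' `"interactor"`.
#'
#' @param ppi An `igraph` from [merge_ppi()].
#' @param seeds Character vector of seed gene symbols.
#' @return An undirected `igraph`.
#' @export
neighbor_subgraph <- function(ppi, seeds) {
  seeds <- unique(seeds)
  missing <- setdiff(seeds, igraph::V(ppi)$name)
  if (length(missing)) {
    ppi <- igraph::add_vertices(ppi, length(missing), name = missing,
                                role = "interactor")
  }
  nbrs <- unique(unlist(lapply(
    igraph::adjacent_vertices(ppi, v = seeds), igraph::as_ids
  )))
  sub <- igraph::induced_subgraph(ppi, vids = unique(c(seeds, nbrs)))
  igraph::V(sub)$role <- ifelse(igraph::V(sub)$name %in% seeds,
                                "seed", "interactor")
  sub
}

#' Export a network in SIF or GraphML format
#'
#' SIF lines are `source<TAB>relation<TAB>target` with relation `targets`
#' for bipartite miRNA-gene networks (miRNA endpoint first) and `pp` for PPI
#' networks, rows sorted, so output is byte-stable for a fixed input. GraphML
#' is written through igraph and carries the node `mode`/`role` and edge
#' `sources` attributes.
#'
#' @param network An `igraph` from [build_bipartite()], [merge_ppi()], or
#'   [neighbor_subgraph()].
#' @param path Destination file path.
#' @param format `"sif"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  bipartite <- "mode" %in% igraph::vertex_attr_names(network)
  el <- igraph::as_edgelist(network, names = TRUE)
  if (nrow(el) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (bipartite) {
    modes <- stats::setNames(igraph::V(network)$mode, igraph::V(network)$name)
    swap <- modes[el[, 1]] != "mirna"
    el[swap, ] <- el[swap, 2:1]
    relation <- "targets"
  } else {
    el <- t(apply(el, 1, sort))
    relation <- "pp"
  }
  lines <- sort(paste(el[, 1], relation, el[, 2], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
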