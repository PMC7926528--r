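#' Alias map for curated amelogenesis imperfecta gene symbols
#'
#' The curated source tables contain a handful of spelling variants and typos
#' for well-known HGNC symbols (for example `FMA20A` for `FAM20A`, `AIRA` for
#' `AIRE`, `PCTN` for `PCNT`). Without an explicit alias map the union count of
#' the registry and every downstream tally silently drifts, so the map is
#' shipped as data and applied at load time.
#'
#' @return Named character vector mapping alias spellings (names) to canonical
#'   uppercase HGNC symbols (values).
#' @export
#' @examples
#' ai_alias_map()[["FMA20A"]]
ai_alias_map <- function() {
  c(
    FMA20A   = "FAM20A",
    AIRA     = "AIRE",
    PCTN     = "PCNT",
    EPNN1    = "ENPP1",
    C4ORF26  = "ODAPH"
  )
}

#' Normalize gene symbols
#'
#' Trims whitespace and markdown artefacts, uppercases, and applies an alias
#' map. Symbols that are still non-alphanumeric (hyphens allowed) after cleanup
#' raise an error naming the offending token.
#'
#' @param x Character vector of raw gene symbols.
#' @param aliases Named character vector; see [ai_alias_map()].
#' @return Character vector of normalized uppercase symbols.
#' @export
#' @examples
#' normalize_symbols(c("amelx", " FMA20A "))
normalize_symbols <- function(x, aliases = ai_alias_map()) {
  x <- toupper(gsub("[*_ ]", "", trimws(as.character(x))))
  if (any(x == "" | is.na(x))) {
    rlang::abort("empty gene symbol after cleanup")
  }
  bad <- grepl("[^A-Z0-9-]", x)
  if (any(bad)) {
    rlang::abort(paste0(
      "unmappable gene symbol(s): ",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  names(aliases) <- toupper(names(aliases))
  hit <- x %in% names(aliases)
  x[hit] <- unname(aliases[x[hit]])
  x
}

# split a delimited gene-list cell into a character vector
split_gene_list <- function(cell) {
  out <- unlist(strsplit(as.character(cell), "[,;]"))
  out <- trimws(out)
  out[nzchar(out)]
}

# canonical category spellings accepted for the inheritance table
.inheritance_levels <- c(
  autosomal_recessive = "AR", ar = "AR", AR = "AR",
  autosomal_dominant = "AD", ad = "AD", AD = "AD",
  x_linked_recessive = "XLR", xlr = "XLR", XLR = "XLR",
  x_linked_dominant = "XLD", xld = "XLD", XLD = "XLD"
)

.phenotype_levels <- c(
  "hypoplastic", "hypomaturation", "hypocalcified",
  "taurodontism_type", "unspecified"
)

# parse one classification table (columns: category, genes) into a long tibble
parse_class_table <- function(tbl, what, aliases) {
  if (is.null(tbl)) {
    return(NULL)
  }
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0L) {
    rlang::abort(paste0("empty ", what, " table"))
  }
  if (!all(c("category", "genes") %in% names(tbl))) {
    rlang::abort(paste0(what, " table needs columns 'category' and 'genes'"))
  }
  tbl |>
    dplyr::mutate(genes = purrr::map(.data$genes, split_gene_list)) |>
    tidyr::unnest("genes") |>
    dplyr::mutate(
      raw = .data$genes,
      symbol = normalize_symbols(.data$genes, aliases),
      category = as.character(.data$category)
    ) |>
    dplyr::distinct(.data$category, .data$symbol, .data$raw)
}

#' Load the curated disease gene registry from classification tables
#'
#' Builds the gene registry from up to three tabular inputs, each with a
#' `category` column and a delimited `genes` column: the isolated/syndromic
#' table (categories `isolated`, `syndromic`), the inheritance table
#' (`autosomal_recessive`, `autosomal_dominant`, `x_linked_recessive`,
#' `x_linked_dominant`, or the shorthand `AR`/`AD`/`XLR`/`XLD`), and the
#' phenotype table (Witkop categories). The registry's symbol universe is the
#' union over all rows of all supplied tables, with alias normalization
#' applied before deduplication.
#'
#' @param isolated_syndromic,inheritance,phenotype Data frames with columns
#'   `category` and `genes` (comma- or semicolon-delimited). Only
#'   `isolated_syndromic` is required.
#' @param aliases Alias map, see [ai_alias_map()].
#' @param provenance Free-text source tag stored as an attribute.
#' @return A tibble of class `ai_registry`, one row per unique symbol, columns
#'   `symbol`, `aliases`, `syndromic_status`, `inheritance`, `phenotype`
#'   (multi-valued fields semicolon-delimited), sorted by symbol.
#' @export
#' @examples
#' t1 <- tibble::tibble(category = c("isolated", "syndromic"),
#'                      genes = c("A1, B1", "B1, C1"))
#' load_registry(t1)
load_registry <- function(isolated_syndromic,
                          inheritance = NULL,
                          phenotype = NULL,
                          aliases = ai_alias_map(),
                          provenance = "curated") {
  t1 <- parse_class_table(isolated_syndromic, "isolated/syndromic", aliases)
  t2 <- parse_class_table(inheritance, "inheritance", aliases)
  t3 <- parse_class_table(phenotype, "phenotype", aliases)

  ok1 <- c("isolated", "syndromic")
  if (!all(t1$category %in% ok1)) {
    rlang::abort("isolated/syndromic table categories must be 'isolated' or 'syndromic'")
  }
  if (!is.null(t2)) {
    if (!all(t2$category %in% names(.inheritance_levels))) {
      rlang::abort("unknown inheritance category in table")
    }
    t2$category <- unname(.inheritance_levels[t2$category])
  }

  symbols <- sort(unique(c(t1$symbol, t2$symbol, t3$symbol)))

  status_of <- function(s) {
    rows <- unique(t1$category[t1$symbol == s])
    if (length(rows) == 2L) "both"
    else if (length(rows) == 1L) rows
    else NA_character_
  }
  collect <- function(tbl, s, order = NULL) {
    if (is.null(tbl)) return("")
    v <- unique(tbl$category[tbl$symbol == s])
    if (!is.null(order)) v <- order[order %in% v] else v <- sort(v)
    paste(v, collapse = ";")
  }
  alias_of <- function(s) {
    raw <- unique(c(t1$raw[t1$symbol == s], t2$raw[t2$symbol == s],
                    t3$raw[t3$symbol == s]))
    raw <- toupper(gsub("[*_ ]", "", raw))
    raw <- setdiff(raw, s)
    paste(sort(raw), collapse = ";")
  }

  out <- tibble::tibble(
    symbol = symbols,
    aliases = vapply(symbols, alias_of, character(1), USE.NAMES = FALSE),
    syndromic_status = vapply(symbols, status_of, character(1), USE.NAMES = FALSE),
    inheritance = vapply(symbols, function(s)
      collect(t2, s, c("AR", "AD", "XLR", "XLD")), character(1), USE.NAMES = FALSE),
    phenotype = vapply(symbols, function(s)
      collect(t3, s, .phenotype_levels), character(1), USE.NAMES = FALSE)
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("ai_registry", class(out))
  out
}

#' Tally registry genes by inheritance mode
#'
#' Counts unique symbols per inheritance category: autosomal recessive (AR),
#' autosomal dominant (AD), the AR-and-AD overlap, X-linked recessive and
#' dominant separately, and their combined X-linked count (the figure the
#' curation reports).
#'
#' @param registry An `ai_registry` tibble with inheritance labels.
#' @return Tibble with columns `category`
#'   (`AR`, `AD`, `AR_AD`, `XLR`, `XLD`, `X_linked`) and `n_genes`.
#' @export
tally_by_inheritance <- function(registry) {
  inh <- strsplit(registry$inheritance, ";", fixed = TRUE)
  if (all(lengths(inh) == 0L)) {
    rlang::abort("registry carries no inheritance labels")
  }
  has <- function(lab) vapply(inh, function(v) lab %in% v, logical(1))
  tibble::tibble(
    category = c("AR", "AD", "AR_AD", "XLR", "XLD", "X_linked"),
    n_genes = c(
      sum(has("AR")), sum(has("AD")), sum(has("AR") & has("AD")),
      sum(has("XLR")), sum(has("XLD")), sum(has("XLR") | has("XLD"))
    )
  )
}

#' Tally registry genes by isolated/syndromic status
#'
#' @param registry An `ai_registry` tibble.
#' @return One-row tibble: `n_isolated` and `n_syndromic` (row counts, shared
#'   genes counted in both), `n_shared`, `n_total` (unique symbols carrying a
#'   status), and `isolated_fraction` = `n_isolated / n_total`.
#' @export
tally_by_syndromic <- function(registry) {
  st <- registry$syndromic_status
  n_iso <- sum(st %in% c("isolated", "both"))
  n_syn <- sum(st %in% c("syndromic", "both"))
  n_both <- sum(st %in% "both")
  n_tot <- sum(!is.na(st))
  tibble::tibble(
    n_isolated = n_iso,
    n_syndromic = n_syn,
    n_shared = n_both,
    n_total = n_tot,
    isolated_fraction = if (n_tot > 0) n_iso / n_tot else NA_real_
  )
}

#' Tally registry genes by enamel phenotype category
#'
#' Counts unique symbols per Witkop-style phenotype row; a gene may contribute
#' to several rows.
#'
#' @param registry An `ai_registry` tibble.
#' @return Tibble with columns `category` and `n_genes`, canonical phenotype
#'   order; empty tibble when no phenotype labels are present.
#' @export
tally_by_phenotype <- function(registry) {
  long <- tibble::tibble(
    symbol = rep(registry$symbol, lengths(strsplit(registry$phenotype, ";"))),
    category = unlist(strsplit(registry$phenotype, ";"))
  )
  if (nrow(long) == 0L) {
    return(tibble::tibble(category = character(), n_genes = integer()))
  }
  long |>
    dplyr::distinct(.data$category, .data$symbol) |>
    dplyr::count(.data$category, name = "n_genes") |>
    dplyr::arrange(match(.data$category,
                         c(.phenotype_levels, sort(unique(.data$category)))))
}

#' Cohen's kappa inter-rater agreement
#'
#' Chance-corrected agreement between two raters over the same items:
#' `(p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement and `p_e` the
#' chance agreement implied by the raters' marginal label frequencies. When
#' both raters assign one identical constant label (`p_e = 1`), kappa is
#' defined as 1 by convention.
#'
#' @param ratings_a,ratings_b Equal-length vectors of categorical labels.
#' @return Kappa statistic in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(c("x", "y", "x"), c("x", "y", "x"))
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    rlang::abort("rating vectors must have equal length")
  }
  if (length(ratings_a) == 0L) {
    rlang::abort("rating vectors must be non-empty")
  }
  labs <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = labs)
  b <- factor(as.character(ratings_b), levels = labs)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (isTRUE(all.equal(p_e, 1))) {
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Read / write a serialized gene registry
#'
#' TSV with one record per line, columns `symbol`, `aliases`,
#' `syndromic_status`, `inheritance`, `phenotype`; multi-valued fields
#' semicolon-delimited; sorted by symbol so fixtures diff cleanly.
#'
#' @param path File path.
#' @return `read_registry()` returns an `ai_registry` tibble.
#' @export
read_registry <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  need <- c("symbol", "aliases", "syndromic_status", "inheritance", "phenotype")
  if (!all(need %in% names(out))) {
    rlang::abort("registry TSV is missing required columns")
  }
  out <- dplyr::arrange(out[need], .data$symbol)
  out$syndromic_status[out$syndromic_status == ""] <- NA_character_
  class(out) <- c("ai_registry", class(out))
  out
}

#' @rdname read_registry
#' @param registry An `ai_registry` tibble.
#' @export
write_registry <- function(registry, path) {
  out <- dplyr::arrange(tibble::as_tibble(registry), .data$symbol)
  out$syndromic_status[is.na(out$syndromic_status)] <- ""
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Tab-delimited gene-set format: set name, description, then one gene per
#' field. Gene symbols are normalized on read.
#'
#' @param path File path.
#' @param aliases Alias map applied to member symbols on read.
#' @return `read_gmt()` returns a tibble with columns `name`, `description`,
#'   and list-column `genes`.
#' @export
read_gmt <- function(path, aliases = ai_alias_map()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  bad <- which(lengths(rows) < 3L)
  if (length(bad)) {
    rlang::abort(paste0("malformed GMT line(s): ", paste(bad, collapse = ", ")))
  }
  tibble::tibble(
    name = vapply(rows, `[[`, character(1), 1L),
    description = vapply(rows, `[[`, character(1), 2L),
    genes = lapply(rows, function(r)
      sort(unique(normalize_symbols(r[-(1:2)], aliases))))
  )
}

#' @rdname read_gmt
#' @param sets Tibble with columns `name`, `description`, list-column `genes`.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets[c("name", "description", "genes")],
    function(name, description, genes) {
      paste(c(name, description, sort(unique(genes))), collapse = "\t")
    })
  writeLines(lines, path)
  invisible(path)
}
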