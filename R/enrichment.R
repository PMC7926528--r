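check_hyper_args <- function(k, n, m, N) {
  args <- vctrs::vec_recycle_common(k = k, n = n, m = m, N = N)
  k <- args$k; n <- args$n; m <- args$m; N <- args$N
  if (any(k < 0 | n < 0 | m < 0 | N < 1)) {
    rlang::abort("k, n, m must be non-negative and N positive")
  }
  if (any(n > N) || any(m > N)) {
    rlang::abort("n and m must not exceed the universe size N")
  }
  if (any(k > pmin(n, m)) || any(k < pmax(0, m + n - N))) {
    rlang::abort("k outside [max(0, m + n - N), min(n, m)]: impossible overlap")
  }
  args
}

#' One-sided hypergeometric upper-tail p-value
#'
#' Probability of observing an overlap at least as large as `k` when `n`
#' items are drawn without replacement from a universe of `N` genes of which
#' `m` belong to the disease set: `P(X >= k)` for
#' `X ~ Hypergeometric(N, m, n)`. This is the one-sided Fisher exact test for
#' over-representation, computed via the exact survival function (no normal
#' approximation). Vectorized over all arguments.
#'
#' @param k Observed overlap count(s).
#' @param n Number of targets drawn (per miRNA or term).
#' @param m Disease-set size within the universe.
#' @param N Universe (background) size.
#' @return p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_upper_tail(k = 1, n = 2, m = 2, N = 4) # 5/6
hypergeom_upper_tail <- function(k, n, m, N) {
  a <- check_hyper_args(k, n, m, N)
  stats::phyper(a$k - 1, a$m, a$N - a$m, a$n, lower.tail = FALSE)
}

#' Two-sided Fisher exact p-value
#'
#' Exact two-sided p on the 2x2 table with fixed margins (`n` targets, `m`
#' disease genes, universe `N`): the sum of point probabilities of all tables
#' at least as extreme as the observed one, i.e. with hypergeometric point
#' probability no larger than the observed table's (ties admitted within
#' relative tolerance 1e-7). Vectorized over all arguments.
#'
#' @inheritParams hypergeom_upper_tail
#' @return p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' fisher_two_sided(k = 2, n = 2, m = 2, N = 4) # 1/3
fisher_two_sided <- function(k, n, m, N) {
  a <- check_hyper_args(k, n, m, N)
  purrr::pmap_dbl(a, function(k, n, m, N) {
    x <- 0:min(n, m)
    d <- stats::dhyper(x, m, N - m, n)
    p_obs <- d[x == k]
    min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
  })
}

#' Enrichment test configuration
#'
#' Bundles the background parameters that dominate every exact-test p-value:
#' the universe size `N`, the effective disease-set size `m`, the test
#' variant, the significance level, and the multiplicity adjustment. `N` and
#' `m` must be supplied explicitly (or recovered with [invert_background()]);
#' they are never silently defaulted.
#'
#' @param universe_size Background universe size `N`.
#' @param set_size Disease-set size `m` within the universe.
#' @param variant `"hypergeom_upper"` (one-sided, default) or
#'   `"fisher_two_sided"`.
#' @param alpha Significance level in (0, 1).
#' @param adjust `"none"` (raw p, the default for the miRNA screen) or `"bh"`.
#' @return A list of class `ai_test_config`.
#' @export
test_config <- function(universe_size, set_size,
                        variant = c("hypergeom_upper", "fisher_two_sided"),
                        alpha = 0.05, adjust = c("none", "bh")) {
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  universe_size <- as.integer(universe_size)
  set_size <- as.integer(set_size)
  if (universe_size < 1L || set_size < 1L || set_size > universe_size) {
    rlang::abort("need 1 <= set_size <= universe_size")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must lie in (0, 1)")
  }
  structure(
    list(universe_size = universe_size, set_size = set_size,
         variant = variant, alpha = alpha, adjust = adjust),
    class = "ai_test_config"
  )
}

variant_fun <- function(variant) {
  switch(variant,
    hypergeom_upper = hypergeom_upper_tail,
    fisher_two_sided = fisher_two_sided,
    rlang::abort(paste0("unknown test variant '", variant, "'"))
  )
}

#' Per-miRNA exact-test enrichment of a disease gene set
#'
#' For every miRNA with at least one catalogued target, counts its distinct
#' targets `n` (within the catalog universe when one is set), the overlap `k`
#' with the disease gene set, and computes the exact-test p-value under the
#' configured background `(m, N)`. Results are sorted by p-value, ties broken
#' by miRNA identifier, so output order is total and reproducible.
#'
#' @param catalog An `ai_catalog`.
#' @param gene_set Character vector of disease gene symbols.
#' @param config An [test_config()] object.
#' @return Tibble of class `ai_enrichment`: `mirna`, `overlap_genes`
#'   (list-column, sorted), `n_targets`, `k_overlap`, `p_value`, `p_adjusted`
#'   (NA unless `adjust = "bh"`), `significant`, `rank`. The `alpha` used is
#'   stored as an attribute.
#' @export
enrich <- function(catalog, gene_set, config) {
  stopifnot(inherits(config, "ai_test_config"))
  gene_set <- unique(gene_set)
  universe <- attr(catalog, "universe")
  pairs <- dplyr::distinct(tibble::as_tibble(catalog)[c("mirna", "gene")])
  if (!is.null(universe)) {
    pairs <- dplyr::filter(pairs, .data$gene %in% universe)
    if (length(intersect(gene_set, universe)) == 0L) {
      rlang::abort("gene set does not intersect the catalog universe (m = 0)")
    }
  }
  res <- pairs |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(
      overlap_genes = list(sort(intersect(.data$gene, gene_set))),
      n_targets = dplyr::n_distinct(.data$gene),
      .groups = "drop"
    ) |>
    dplyr::mutate(k_overlap = lengths(.data$overlap_genes))
  if (nrow(res) > 0L && any(res$n_targets > config$universe_size)) {
    rlang::abort("a miRNA has more targets than the universe size N")
  }
  res$p_value <- if (nrow(res)) {
    variant_fun(config$variant)(res$k_overlap, res$n_targets,
                                config$set_size, config$universe_size)
  } else {
    numeric()
  }
  res$p_adjusted <- if (config$adjust == "bh" && nrow(res)) {
    benjamini_hochberg(res$p_value)
  } else {
    rep(NA_real_, nrow(res))
  }
  res <- res |>
    dplyr::arrange(.data$p_value, .data$mirna) |>
    dplyr::mutate(
      significant = .data$p_value < config$alpha,
      rank = dplyr::row_number()
    )
  attr(res, "alpha") <- config$alpha
  attr(res, "config") <- config
  class(res) <- c("ai_enrichment", class(res))
  res
}

#' Rows of an enrichment result passing the significance filter
#'
#' @param results An `ai_enrichment` tibble.
#' @return The significant rows, same column layout.
#' @export
filter_significant <- function(results) {
  dplyr::filter(results, .data$significant)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up procedure with enforced monotonicity, capped at 1;
#' the input order is preserved in the output.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis against a gene-set collection
#'
#' Generic ORA engine: each term of the collection plays the role a miRNA
#' target list plays in [enrich()]. Terms are first intersected with the
#' universe and filtered to `min_size <= |term| <= max_size` (the usual guard
#' against uninformative tiny or giant terms), then tested with the exact
#' machinery and BH-adjusted across retained terms.
#'
#' @param term_db Tibble as returned by [read_gmt()]: `name`, `description`,
#'   list-column `genes`.
#' @param query_set Character vector of query gene symbols (the disease set).
#' @param universe Character vector: the background universe; must contain the
#'   query set.
#' @param min_size,max_size Term-size bounds after universe intersection.
#' @param variant Test variant, see [test_config()].
#' @param alpha Significance level applied to adjusted p-values.
#' @return Tibble of class `ai_enrichment` with `term`, `description`,
#'   `overlap_genes`, `n_genes`, `k_overlap`, `p_value`, `p_adjusted`,
#'   `significant`, `rank`.
#' @export
ora_terms <- function(term_db, query_set, universe,
                      min_size = 5L, max_size = 200L,
                      variant = "hypergeom_upper", alpha = 0.05) {
  universe <- unique(universe)
  query_set <- unique(query_set)
  if (!all(query_set %in% universe)) {
    rlang::abort("query set must be contained in the universe")
  }
  terms <- term_db |>
    dplyr::mutate(genes = lapply(.data$genes, intersect, universe),
                  n_genes = lengths(.data$genes)) |>
    dplyr::filter(.data$n_genes >= min_size, .data$n_genes <= max_size)
  if (nrow(terms) == 0L) {
    rlang::warn("no term survives the size filter")
    out <- tibble::tibble(
      term = character(), description = character(),
      overlap_genes = list(), n_genes = integer(), k_overlap = integer(),
      p_value = numeric(), p_adjusted = numeric(),
      significant = logical(), rank = integer()
    )
    class(out) <- c("ai_enrichment", class(out))
    return(out)
  }
  out <- terms |>
    dplyr::mutate(
      term = .data$name,
      overlap_genes = lapply(.data$genes, function(g) sort(intersect(g, query_set))),
      k_overlap = lengths(.data$overlap_genes)
    )
  out$p_value <- variant_fun(variant)(out$k_overlap, out$n_genes,
                                      length(query_set), length(universe))
  out$p_adjusted <- benjamini_hochberg(out$p_value)
  out <- out |>
    dplyr::arrange(.data$p_value, .data$term) |>
    dplyr::mutate(significant = .data$p_adjusted < alpha,
                  rank = dplyr::row_number()) |>
    dplyr::select("term", "description", "overlap_genes", "n_genes",
                  "k_overlap", "p_value", "p_adjusted", "significant", "rank")
  attr(out, "alpha") <- alpha
  class(out) <- c("ai_enrichment", class(out))
  out
}

#' Write an enrichment result as TSV
#'
#' Fixed column order mirroring the published per-miRNA table layout:
#' `mirna` (or `term`), `overlap_genes` (comma-joined, alphabetical),
#' `n_targets`, `k_overlap`, `p_value`, `p_adjusted`, `significant` (0/1).
#' p-values are printed with 8 significant digits.
#'
#' @param results An `ai_enrichment` tibble.
#' @param path File path.
#' @export
write_enrichment <- function(results, path) {
  id_col <- if ("mirna" %in% names(results)) "mirna" else "term"
  n_col <- if ("n_targets" %in% names(results)) "n_targets" else "n_genes"
  out <- tibble::tibble(
    mirna = results[[id_col]],
    overlap_genes = vapply(results$overlap_genes,
                           function(g) paste(sort(g), collapse = ","),
                           character(1)),
    n_targets = results[[n_col]],
    k_overlap = results$k_overlap,
    p_value = formatC(results$p_value, digits = 8, format = "g"),
    p_adjusted = ifelse(is.na(results$p_adjusted), "",
                        formatC(results$p_adjusted, digits = 8, format = "g")),
    significant = as.integer(results$significant)
  )
  names(out)[1] <- id_col
  names(out)[3] <- n_col
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
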