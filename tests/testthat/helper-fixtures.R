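# toy classification tables covering all three label axes
toy_tables <- function() {
  list(
    isolated_syndromic = tibble::tibble(
      category = c("isolated", "syndromic"),
      genes = c("GENEA, GENEC", "GENEB, GENEC")
    ),
    inheritance = tibble::tibble(
      category = c("autosomal_recessive", "autosomal_dominant"),
      genes = c("GENEA, GENEB", "GENEB")
    ),
    phenotype = tibble::tibble(
      category = c("hypoplastic", "hypomaturation"),
      genes = c("GENEA, GENEB", "GENEB")
    )
  )
}

# catalog from a plain pair data frame
toy_catalog <- function(pairs, source_tag = "toy") {
  read_target_source(pairs, dialect = "pairs", source_tag = source_tag)
}

# brute-force hypergeometric upper tail: enumerate all C(N, n) draws of n
# items from a universe with m marked successes; fraction with >= k marked
brute_force_upper_tail <- function(k, n, m, N) {
  universe <- seq_len(N)
  marked <- seq_len(m)
  draws <- utils::combn(universe, n)
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= k)
  mean(hits)
}

# random small catalogs for property checks
random_catalog <- function(seed, n_mirnas = 5, n_genes = 12, sources = 3) {
  withr::with_seed(seed, {
    lapply(seq_len(sources), function(s) {
      pairs <- expand.grid(
        mirna = sprintf("hsa-miR-%d", seq_len(n_mirnas)),
        gene = sprintf("G%02d", seq_len(n_genes)),
        stringsAsFactors = FALSE
      )
      pairs <- pairs[runif(nrow(pairs)) < 0.3, ]
      toy_catalog(pairs, source_tag = paste0("s", s))
    })
  })
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
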