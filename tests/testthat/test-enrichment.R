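test_that("hypergeometric upper tail matches hand-derived values", {
  expect_equal(hypergeom_upper_tail(0, 3, 2, 10), 1)
  expect_equal(hypergeom_upper_tail(1, 2, 2, 4), 5 / 6)
  expect_equal(hypergeom_upper_tail(2, 2, 2, 4), 1 / 6)
  expect_error(hypergeom_upper_tail(3, 2, 2, 4), "impossible")
  expect_error(hypergeom_upper_tail(1, 5, 2, 4), "exceed")
})

test_that("upper tail equals brute-force enumeration over draw subsets", {
  for (N in c(6, 9, 12)) {
    for (n in c(2, 4, min(6, N - 1))) {
      for (m in c(2, 4)) {
        for (k in max(0, m + n - N):min(n, m)) {
          expect_equal(
            hypergeom_upper_tail(k, n, m, N),
            brute_force_upper_tail(k, n, m, N),
            tolerance = 1e-12,
            label = sprintf("k=%d n=%d m=%d N=%d", k, n, m, N)
          )
        }
      }
    }
  }
})

test_that("hypergeometric pmf normalizes and tails are monotone", {
  for (N in c(50, 200, 500)) {
    m <- round(N / 5); n <- round(N / 3)
    expect_lt(abs(sum(stats::dhyper(0:min(n, m), m, N - m, n)) - 1), 1e-12)
    # p strictly decreasing in k; parameters keep the whole tail inside
    # double precision (neither saturated at 1 nor underflowed at 0)
    n_mono <- max(5, round(N / 10))
    p_k <- hypergeom_upper_tail(0:min(n_mono, m, 25), n_mono, m, N)
    expect_true(all(diff(p_k) < 0))
  }
  # p non-increasing in N for fixed k >= 1
  p_N <- hypergeom_upper_tail(2, 20, 10, seq(60, 600, by = 20))
  expect_true(all(diff(p_N) <= 1e-15))
})

test_that("two-sided Fisher p agrees with the reference implementation", {
  # minimal balanced table: point probs {1/6, 4/6, 1/6}
  expect_equal(fisher_two_sided(2, 2, 2, 4), 1 / 3)
  withr::with_seed(11, {
    for (i in 1:25) {
      N <- sample(8:40, 1)
      m <- sample(2:(N - 2), 1)
      n <- sample(2:(N - 2), 1)
      k_lo <- max(0, m + n - N)
      k <- sample(k_lo:min(n, m), 1)
      tab <- matrix(c(k, m - k, n - k, N - m - n + k), 2)
      expect_equal(
        fisher_two_sided(k, n, m, N),
        stats::fisher.test(tab)$p.value,
        tolerance = 1e-7,
        label = sprintf("k=%d n=%d m=%d N=%d", k, n, m, N)
      )
      # two-sided dominates the upper tail above the table's expectation
      if (k > m * n / N) {
        expect_gte(fisher_two_sided(k, n, m, N) + 1e-12,
                   hypergeom_upper_tail(k, n, m, N))
      }
    }
  })
})

test_that("enrich scores each miRNA against the configured background", {
  cfg <- test_config(universe_size = 4, set_size = 2)
  cat1 <- toy_catalog(data.frame(mirna = c("m1", "m1"), gene = c("GA", "GX")))
  res <- enrich(cat1, c("GA", "GB"), cfg)
  expect_s3_class(res, "ai_enrichment")
  expect_equal(res$n_targets, 2L)
  expect_equal(res$k_overlap, 1L)
  expect_equal(res$overlap_genes[[1]], "GA")
  expect_equal(res$p_value, 5 / 6)

  # no targeted set gene: all k = 0, p = 1, nothing significant
  null_res <- enrich(cat1, c("GY", "GZ"), test_config(10, 2))
  expect_true(all(null_res$k_overlap == 0L))
  expect_true(all(null_res$p_value == 1))
  expect_equal(nrow(filter_significant(null_res)), 0L)

  expect_error(enrich(cat1, "GA", test_config(1, 1)), "universe size")
})

test_that("enrich output is invariant to catalog row order with total sorting", {
  pairs <- data.frame(
    mirna = c("m2", "m1", "m3", "m1", "m2"),
    gene = c("GA", "GA", "GB", "GC", "GD")
  )
  cfg <- test_config(universe_size = 100, set_size = 10)
  a <- enrich(toy_catalog(pairs), c("GA", "GB"), cfg)
  b <- enrich(toy_catalog(pairs[sample(nrow(pairs)), ]), c("GA", "GB"), cfg)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_equal(a$rank, seq_len(nrow(a)))
  # ties in p resolve by miRNA identifier
  expect_equal(order(a$p_value, a$mirna), seq_len(nrow(a)))
})

test_that("Benjamini-Hochberg step-up matches the worked example", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(3, {
    p <- runif(50)
    adj <- benjamini_hochberg(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # significance order consistent with raw order
    expect_equal(order(adj, p), order(p))
  })
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ORA filters terms by size and applies BH across retained terms", {
  universe <- sprintf("U%02d", 1:20)
  query <- universe[1:5]
  db <- tibble::tibble(
    name = c("hit", "small", "other"),
    description = "",
    genes = list(universe[1:5], universe[1:4], universe[6:11])
  )
  res <- ora_terms(db, query, universe, min_size = 5, max_size = 200)
  expect_false("small" %in% res$term)
  hit <- res[res$term == "hit", ]
  expect_equal(hit$p_value, 1 / choose(20, 5))
  expect_equal(hit$rank, 1L)
  expect_true(all(res$p_adjusted >= res$p_value))

  expect_warning(
    none <- ora_terms(db, query, universe, min_size = 10, max_size = 200),
    "size filter"
  )
  expect_equal(nrow(none), 0L)
  expect_error(ora_terms(db, c(query, "ZZZ"), universe), "contained")
})

test_that("enrichment TSV export uses the fixed published column layout", {
  cfg <- test_config(universe_size = 4, set_size = 2)
  cat1 <- toy_catalog(data.frame(mirna = c("m1", "m1"), gene = c("GA", "GX")))
  res <- enrich(cat1, c("GA", "GB"), cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  lines <- readLines(path)
  expect_equal(lines[1],
               "mirna\toverlap_genes\tn_targets\tk_overlap\tp_value\tp_adjusted\tsignificant")
  expect_match(lines[2], "0.83333333")
})
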