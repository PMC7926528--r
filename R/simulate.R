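#' Configuration for the synthetic catalog generator
#'
#' States the simulated world for calibration and power studies: a gene
#' universe of `n_genes` synthetic symbols, `n_mirnas` miRNAs whose targets
#' are drawn independently per (miRNA, gene) pair with probability
#' `target_prob`, and a disease set of `set_size` genes sampled uniformly
#' without replacement. Planted "enriched" miRNAs raise the inclusion
#' probability on disease genes to `min(1, target_prob * overlap_boost)`,
#' leaving background targeting untouched so power reflects overlap rather
#' than target-count inflation. Defaults mirror the conditions of the real
#' screen: a protein-coding-scale universe of 16,000 genes (the background
#' recovered by inversion is ~15,800), a 56-gene disease set, 200 miRNAs, and
#' a 1% per-pair targeting rate giving ~160 targets per miRNA, the order of
#' magnitude of the printed target counts.
#'
#' All generators are pure functions of this configuration: randomness comes
#' from R's default Mersenne-Twister generator with the post-3.6.0
#' "Rejection" sampling kind, seeded locally, so results are reproducible
#' across platforms for a given R version family.
#'
#' @param seed Integer seed.
#' @param n_genes Universe size `N`.
#' @param n_mirnas Number of miRNAs `M`.
#' @param target_prob Per-(miRNA, gene) inclusion probability `f` in (0, 1).
#' @param set_size Disease-set size `m`.
#' @param n_planted Number of enriched miRNAs to plant.
#' @param overlap_boost Multiplier (>= 1) on `f` restricted to disease genes
#'   for planted miRNAs.
#' @param reps Replicate count for Monte-Carlo estimates.
#' @return A list of class `ai_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 16000L, n_mirnas = 200L,
                       target_prob = 0.01, set_size = 56L,
                       n_planted = 0L, overlap_boost = 1, reps = 50L) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_mirnas = as.integer(n_mirnas), target_prob = target_prob,
    set_size = as.integer(set_size), n_planted = as.integer(n_planted),
    overlap_boost = overlap_boost, reps = as.integer(reps)
  )
  if (cfg$target_prob <= 0 || cfg$target_prob >= 1) {
    rlang::abort("target_prob must lie strictly in (0, 1)")
  }
  if (cfg$set_size > cfg$n_genes) {
    rlang::abort("set_size must not exceed n_genes")
  }
  if (cfg$n_planted > cfg$n_mirnas) {
    rlang::abort("n_planted must not exceed n_mirnas")
  }
  if (cfg$overlap_boost < 1) {
    rlang::abort("overlap_boost must be >= 1")
  }
  structure(cfg, class = "ai_sim_config")
}

sim_gene_names <- function(n) sprintf("G%05d", seq_len(n))
sim_mirna_names <- function(n) sprintf("hsa-miR-sim%04d", seq_len(n))

# draw one catalog; planted miRNAs get boosted inclusion on disease genes.
# Per-pair independent inclusion is realized as two binomial draws (disease
# vs background part), which is the same law and far cheaper than N*M
# uniforms.
draw_catalog <- function(config) {
  genes <- sim_gene_names(config$n_genes)
  mirnas <- sim_mirna_names(config$n_mirnas)
  f <- config$target_prob
  f_dis <- min(1, f * config$overlap_boost)
  disease <- sort(sample(genes, config$set_size))
  background <- setdiff(genes, disease)
  planted <- mirnas[seq_len(config$n_planted)]
  pick <- function(pool, prob) {
    n_hit <- stats::rbinom(1L, length(pool), prob)
    if (n_hit == 0L) character() else sample(pool, n_hit)
  }
  targets <- lapply(mirnas, function(mi) {
    p_dis <- if (mi %in% planted) f_dis else f
    sort(c(pick(disease, p_dis), pick(background, f)))
  })
  catalog <- new_catalog(
    tibble::tibble(
      mirna = rep(mirnas, lengths(targets)),
      gene = unlist(targets),
      sources = "sim"
    ),
    universe = genes
  )
  list(catalog = catalog, gene_set = disease, planted = planted)
}

#' Simulate a null target catalog
#'
#' Every (miRNA, gene) pair is included independently with probability
#' `target_prob`; the disease set is drawn uniformly; no miRNA is enriched.
#' Fully determined by `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return List with `catalog` (an `ai_catalog` whose universe is the full
#'   synthetic gene universe) and `gene_set` (the disease genes).
#' @export
simulate_null_catalog <- function(config) {
  cfg <- config
  cfg$n_planted <- 0L
  cfg$overlap_boost <- 1
  out <- withr::with_seed(cfg$seed, draw_catalog(cfg))
  out[c("catalog", "gene_set")]
}

#' Simulate a catalog with planted enriched miRNAs
#'
#' As [simulate_null_catalog()], but the first `n_planted` miRNAs target
#' disease genes with probability `min(1, target_prob * overlap_boost)`.
#' A saturated alternative (`target_prob * overlap_boost >= 1`), under which
#' planted miRNAs target every disease gene, triggers a warning.
#'
#' @param config An [sim_config()] object with `n_planted >= 1`.
#' @return List with `catalog`, `gene_set`, and `planted` (miRNA
#'   identifiers).
#' @export
plant_enriched_mirnas <- function(config) {
  if (config$target_prob * config$overlap_boost >= 1) {
    rlang::warn("saturated alternative: planted miRNAs target every disease gene")
  }
  withr::with_seed(config$seed, draw_catalog(config))
}

sim_test_config <- function(config, test_config) {
  if (is.null(test_config)) {
    test_config(universe_size = config$n_genes, set_size = config$set_size)
  } else {
    test_config
  }
}

#' Empirical type-I error of the enrichment screen
#'
#' Runs [enrich()] on `reps` independently seeded null catalogs and returns
#' the fraction of (miRNA, replicate) tests with `p < alpha`. Replicate `r`
#' uses seed `seed + r - 1`. Exact tests are conservative under this null, so
#' the rate is expected at or below `alpha`.
#'
#' @param config An [sim_config()] with `n_planted = 0`.
#' @param test_config An [test_config()]; defaults to the simulated world's
#'   own `(m, N)` with the one-sided variant at `alpha = 0.05`.
#' @return One-row tibble: `rate`, `n_tests`, `reps`, `alpha`.
#' @export
type1_error <- function(config, test_config = NULL) {
  if (config$n_planted != 0L) {
    rlang::abort("type-I error requires a null configuration (n_planted = 0)")
  }
  if (config$reps < 100L) {
    rlang::warn("fewer than 100 replicates: noisy type-I estimate")
  }
  tc <- sim_test_config(config, test_config)
  hits <- 0L; total <- 0L
  for (r in seq_len(config$reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_null_catalog(cfg)
    res <- enrich(sim$catalog, sim$gene_set, tc)
    hits <- hits + sum(res$p_value < tc$alpha)
    total <- total + nrow(res)
  }
  tibble::tibble(rate = hits / total, n_tests = total,
                 reps = config$reps, alpha = tc$alpha)
}

#' Empirical power across planted-overlap boosts
#'
#' For each boost value, simulates `reps` catalogs with planted enriched
#' miRNAs and returns the fraction of planted miRNAs detected at
#' `p < alpha`. Power at boost 1 coincides with the type-I error rate (the
#' planted miRNAs are then distributionally null), and is non-decreasing in
#' the boost up to Monte-Carlo error.
#'
#' @param config An [sim_config()] with `n_planted >= 1`.
#' @param test_config See [type1_error()].
#' @param boosts Numeric vector of overlap boosts (>= 1).
#' @return Tibble with one row per boost, sorted: `boost`, `power`,
#'   `n_tests`.
#' @export
power_curve <- function(config, test_config = NULL, boosts = c(1, 5, 20)) {
  if (config$n_planted < 1L) {
    rlang::abort("power requires at least one planted miRNA")
  }
  if (config$reps < 100L) {
    rlang::warn("fewer than 100 replicates: noisy power estimate")
  }
  tc <- sim_test_config(config, test_config)
  boosts <- sort(boosts)
  out <- purrr::imap_dfr(boosts, function(boost, bi) {
    hits <- 0L; total <- 0L
    for (r in seq_len(config$reps)) {
      cfg <- config
      cfg$overlap_boost <- boost
      cfg$seed <- config$seed + (bi - 1L) * config$reps + r - 1L
      sim <- suppressWarnings(plant_enriched_mirnas(cfg))
      res <- enrich(sim$catalog, sim$gene_set, tc)
      planted_rows <- res$mirna %in% sim$planted
      hits <- hits + sum(res$p_value[planted_rows] < tc$alpha)
      total <- total + sum(planted_rows)
    }
    tibble::tibble(boost = boost, power = hits / total, n_tests = total)
  })
  out
}
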