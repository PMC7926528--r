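---
title: "Methods: exact-test miRNA enrichment for amelogenesis imperfecta genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact-test miRNA enrichment for amelogenesis imperfecta genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimirna)
```

## The problem

Amelogenesis imperfecta (AI) is a congenital failure of enamel formation.
Curation of the human genetics literature yields 56 genes in which mutations
or linkage have been reported, classified three ways: isolated versus
syndromic presentation, inheritance mode (autosomal recessive or dominant,
X-linked recessive or dominant), and Witkop enamel phenotype (hypoplastic,
hypomaturation, hypocalcified, taurodontism-associated). MicroRNAs repress
their target mRNAs post-transcriptionally, so a miRNA whose predicted target
list is unusually rich in AI genes is a candidate upstream regulator of
amelogenesis. This package implements that screen end to end, together with
the network views around it and a synthetic-data harness that makes every
stage testable without any database download.

## Gene registry and curation statistics

`load_registry()` unions the gene lists of the three classification tables
into one registry keyed by normalized symbol. Two curation details matter:

* **Alias map.** The source tables contain spelling variants of standard
  HGNC symbols (`FMA20A`/`FAM20A`, `AIRA`/`AIRE`, `PCTN`/`PCNT`,
  `EPNN1`/`ENPP1`, and `ODAPH`, formerly `C4orf26`). `ai_alias_map()` is
  shipped as data and applied at load; without it the union count and every
  downstream tally silently drift. The raw spellings are preserved in the
  registry's `aliases` column so corrections stay visible.
* **Counts are of unique normalized symbols**, never of row occurrences. A
  gene listed under several phenotypes contributes to each row once. The
  X-linked tally is reported both split (XLR, XLD) and combined, because the
  combined figure is the one usually quoted.

With the packaged tables this yields 56 genes, a 17-gene isolated row
(17/56 = 30.4%), 40 autosomal-recessive and 16 autosomal-dominant genes.
The accompanying prose of the curated source is arithmetically inconsistent
in two places (it mentions "15 genes" alongside the 17-row isolated table,
and prints 39/56 = 68.4% where 39/56 = 69.6%); the package follows the
tables, which are self-consistent, and does not target those percentages.
The inheritance table also omits one gene (RUNX1) that the
isolated/syndromic table carries; the registry union is unaffected.

`cohens_kappa()` provides the chance-corrected inter-rater agreement used
during literature screening, `(p_o - p_e)/(1 - p_e)`. When both raters
assign one identical constant label, `p_e = 1` and the ratio is undefined;
the package defines this degenerate case as 1 (perfect agreement), which is
the conventional and least surprising choice.

## Target catalogs

`read_target_source()` reads prediction exports (TargetScan-, miRanda-,
PITA-, miRTarBase-like TSVs) through a named column mapping, normalizing
gene symbols as above and miRNA identifiers to the canonical `hsa-miR-...`
form (arm suffixes kept verbatim; arms are never merged, since the -5p and
-3p mature products have different seed sequences and target sets).
Prediction scores are carried in provenance but ignored by the screen, which
is presence/absence.

`combine_catalogs()` makes the multi-source combination rule explicit. The
default is **union** — the screen being emulated pools four prediction
sources without an intersection rule, and union is the only policy that
reproduces its target counts — but `intersection` and `min_sources(k)` are
available for stricter consensus analyses, and the nesting
`intersection ⊆ min_sources(k) ⊆ union` is enforced by tests.

## The exact test and its background

`enrich()` scores each miRNA with the hypergeometric upper tail
`P(X >= k)`, `X ~ Hypergeometric(N, m, n)` — equivalently the one-sided
Fisher exact test — computed through the exact survival function; no normal
approximation is used anywhere. A two-sided Fisher variant is provided
(summation over all tables with point probability at most the observed
one, ties admitted within relative tolerance 1e-7), because screens often
say only "Fisher's exact test". One-sided is the default: enrichment is a
one-sided question, and for overlaps far above expectation (tiny `m·n/N`)
the two variants coincide numerically anyway.

The two integers that dominate every p-value — the universe size `N` and
the effective disease-set size `m` — must be supplied explicitly in
`test_config()`; they are never silently defaulted. Raw p-values are
reported for the per-miRNA screen (matching the printed table's convention
of an unadjusted 0.05 threshold); `benjamini_hochberg()` adjustment is off
by default there and on by default in `ora_terms()`, the generic
over-representation engine, which also applies the usual 5–200 term-size
filter.

## Background inversion

The printed screen gives `(n, k, p)` per miRNA but not `(m, N)` or the test
sidedness. `invert_background()` recovers them by exhaustive integer grid
search — `m` in 40–60, `N` in 1,000–30,000, both variants — minimizing the
sum of squared `log10` p residuals. Numerical choices:

* **Coarse-to-fine:** `N` is scanned at step 100, then at step 1 within
  ±100 of the coarse optimum. The residual surface is smooth enough in `N`
  for this to find the global optimum at desk-scale runtime (~4 s).
* **Deterministic tie-breaks:** smallest `N`, then smallest `m`, then the
  one-sided variant. Residuals differing only at floating-point noise
  (relative 1e-9) are treated as ties; this matters in practice because at
  the recovered background the two variants agree to ~1e-14, and without the
  tolerance the variant label would be decided by rounding noise.
* **log10 scale:** printed p-values span two orders of magnitude; least
  squares on the log scale weights each row's relative error equally.

On the packaged 37-row table the search returns `m = 55`, `N = 15804`,
one-sided, with all rows reproduced to a maximal log10 residual of 0.0007
(~0.16% relative) — a single background does explain the whole printed
table. The recovered `m = 55` (not 56) is consistent with one registry gene
being absent from the screen's effective universe. `synth_inversion_table()`
generates ground-truth tables for the recovery property: whenever the
planted `(m, N, variant)` lies in the grid, the inversion returns it with
zero residual.

## Networks

`build_bipartite()` lays one edge per (miRNA, overlap gene) of the retained
screen rows, so the edge count equals the sum of the overlap counts — an
identity the tests enforce. `merge_ppi()` combines interaction files
(PSI-MITAB 2.5, using identifier columns 1–2 and alias columns 5–6, or plain
2-column edge lists) into one undirected graph: pairs are canonicalized so
`A–B` and `B–A` collapse, provenance is unioned, self-loops are dropped with
a logged count. Identifier reconciliation across databases is deliberately
minimal and offline: a `(gene name)`-tagged MITAB alias is preferred when
present, otherwise the raw identifier is kept verbatim. Degrees of specific
seed genes therefore depend on which database snapshots are merged; printed
degree rankings from any particular snapshot combination are treated as
descriptive, not as test fixtures. Exports (sorted SIF, GraphML) are
byte-stable for a fixed input.

## Synthetic data: the stated world

`sim_config()` fixes the generative model: each (miRNA, gene) pair is
included independently with probability `f`; the disease set is a uniform
draw of `m` genes; planted miRNAs raise the inclusion probability on disease
genes to `min(1, f · boost)`, leaving background targeting untouched so that
power reflects overlap, not target-count inflation. Defaults mirror the real
screen: `N = 16000` (the inverted background is ~15,800), `m = 56`,
`M = 200` miRNAs, `f = 0.01` (~160 targets per miRNA, the order of magnitude
of the printed counts), 50 replicates. Calibration checks run at the
smaller, faster world (`N = 1000`, `m = 50`, `f = 0.02`) so the whole suite
stays under half a minute.

Randomness is R's default Mersenne-Twister with the post-3.6.0 "Rejection"
`sample()` kind, applied in a locally scoped seed; replicate `r` of a
Monte-Carlo estimate uses `seed + r - 1`, so every estimate is a pure
function of its configuration. Independent per-pair inclusion is realized as
two binomial draws (disease and background part), which is the same law at a
fraction of the cost.

What a green calibration test establishes: under exchangeable, independent
targeting, the exact test's type-I error is at or below nominal (exact tests
are conservative) and power rises with the planted overlap. What it does not
establish: behavior under correlated target lists (paralogous gene families,
shared seed sites), prediction-algorithm biases, or universe misspecification
— real prediction databases have all three. The generator is a null model
for the statistic, not a simulator of prediction pipelines.

## Known limitations

* Sequence-level target prediction is out of scope; the package starts from
  prediction exports.
* The effective universe behind a printed screen is recovered, not known;
  `invert_background()` quantifies fit rather than asserting truth, and a
  duplicated or single-row input is non-identifiable (the flat-residual
  region is resolved by the documented tie-break).
* Disease/GO term enrichment results depend on annotation snapshots; only
  the generic ORA machinery is provided, not any snapshot's numbers.
* PPI degree rankings are snapshot-dependent, as above.
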