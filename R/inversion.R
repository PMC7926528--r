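# normalize an inversion input table to columns n, k, p
as_inversion_rows <- function(rows) {
  rows <- tibble::as_tibble(rows)
  nm <- names(rows)
  pick <- function(cands) {
    hit <- intersect(cands, nm)
    if (length(hit) == 0L) {
      rlang::abort(paste0("inversion rows need one of: ",
                          paste(cands, collapse = ", ")))
    }
    rows[[hit[1]]]
  }
  out <- tibble::tibble(
    n = as.integer(pick(c("n", "n_targets"))),
    k = as.integer(pick(c("k", "k_overlap"))),
    p = as.numeric(pick(c("p", "p_value", "p_printed")))
  )
  if (any(out$p <= 0 | out$p >= 1)) {
    rlang::abort("printed p-values must lie strictly in (0, 1)")
  }
  out
}

# sum of squared log10 residuals for one (variant, m) across a vector of N,
# vectorized over the unique (n, k) rows
residuals_over_N <- function(rows, w, m, N_grid, variant) {
  total <- numeric(length(N_grid))
  for (i in seq_len(nrow(rows))) {
    n <- rows$n[i]; k <- rows$k[i]
    if (k > min(n, m)) {
      total <- total + Inf
      next
    }
    pred <- if (variant == "hypergeom_upper") {
      stats::phyper(k - 1, m, N_grid - m, n, lower.tail = FALSE)
    } else {
      x <- 0:min(n, m)
      # point probabilities for every (N, x); tables as extreme as observed
      d <- outer(N_grid, x, function(NN, xx) stats::dhyper(xx, m, NN - m, n))
      p_obs <- d[, match(k, x)]
      pmin(1, rowSums(d * (d <= p_obs * (1 + 1e-7))))
    }
    total <- total + w[i] * (log10(pred) - log10(rows$p[i]))^2
  }
  total
}

#' Recover the unstated enrichment background from a printed results table
#'
#' The published per-miRNA enrichment table prints, for each miRNA, its target
#' count `n`, disease-set overlap `k`, and exact-test p-value -- but neither
#' the background universe size `N`, the effective disease-set size `m`, nor
#' the test sidedness. This operation inverts the table: an exhaustive integer
#' grid search over `m`, `N` (coarse-to-fine: step `coarse_step`, then step 1
#' within `refine_window` of the coarse optimum) and both test variants,
#' minimizing the sum over rows of squared `log10` p residuals. Ties are
#' broken deterministically: smallest `N`, then smallest `m`, then
#' `hypergeom_upper` before `fisher_two_sided`.
#'
#' @param rows Data frame with columns `n`/`n_targets`, `k`/`k_overlap`, and
#'   `p`/`p_value` (at least 2 rows).
#' @param m_range Integer vector of candidate disease-set sizes.
#' @param n_range Length-2 integer range of candidate universe sizes.
#' @param coarse_step Step of the coarse `N` grid.
#' @param refine_window Half-width of the fine `N` window around the coarse
#'   optimum.
#' @param variants Test variants to search over.
#' @return Object of class `ai_inversion`: a list with `m_hat`, `N_hat`,
#'   `variant_hat`, `residual` (sum of squared log10 residuals over all input
#'   rows), and `per_row` (tibble: `n`, `k`, `p_printed`, `p_predicted`,
#'   `log10_residual`). Supports [print()], [generics::tidy()], and
#'   [generics::glance()].
#' @export
#' @examples
#' tab <- synth_inversion_table(m = 10, N = 500, rows = data.frame(
#'   n = c(20, 50), k = c(2, 3)))
#' invert_background(tab, m_range = 8:12, n_range = c(400, 600))
invert_background <- function(rows,
                              m_range = 40:60,
                              n_range = c(1000L, 30000L),
                              coarse_step = 100L,
                              refine_window = 100L,
                              variants = c("hypergeom_upper",
                                           "fisher_two_sided")) {
  rows_all <- as_inversion_rows(rows)
  if (nrow(rows_all) < 2L) {
    rlang::abort("need at least two printed rows to invert")
  }
  m_range <- sort(unique(as.integer(m_range)))
  if (length(m_range) == 0L || n_range[1] > n_range[2]) {
    rlang::abort("empty search range")
  }
  variants <- match.arg(variants, several.ok = TRUE)

  uniq <- rows_all |>
    dplyr::count(.data$n, .data$k, .data$p, name = "w") |>
    dplyr::arrange(.data$n, .data$k)
  N_min_feasible <- max(max(uniq$n), max(m_range))

  # residuals equal up to float noise are ties; ties resolve to the smallest
  # N, then smallest m, then the earlier variant (hypergeom_upper first)
  beats <- function(cand, best) {
    if (!is.finite(cand$res)) return(FALSE)
    if (!is.finite(best$res)) return(TRUE)
    tie <- abs(cand$res - best$res) <= 1e-9 * (1 + min(cand$res, best$res))
    if (!tie) return(cand$res < best$res)
    cand$N < best$N || (cand$N == best$N && cand$m < best$m)
  }

  search_grid <- function(N_grid) {
    best <- list(res = Inf)
    for (variant in variants) {
      for (m in m_range) {
        tot <- residuals_over_N(uniq, uniq$w, m, N_grid, variant)
        i <- which.min(tot)
        cand <- list(res = tot[i], m = m, N = N_grid[i], variant = variant)
        if (beats(cand, best)) {
          best <- cand
        }
      }
    }
    best
  }

  coarse_N <- seq(as.integer(n_range[1]), as.integer(n_range[2]),
                  by = as.integer(coarse_step))
  coarse_N <- coarse_N[coarse_N >= N_min_feasible]
  if (length(coarse_N) == 0L) {
    rlang::abort("no feasible N in the search range")
  }
  coarse <- search_grid(coarse_N)

  fine_N <- seq(max(N_min_feasible, n_range[1], coarse$N - refine_window),
                min(n_range[2], coarse$N + refine_window))
  best <- search_grid(fine_N)

  fit <- variant_fun(best$variant)
  per_row <- rows_all |>
    dplyr::mutate(
      p_predicted = fit(.data$k, .data$n, best$m, best$N),
      log10_residual = abs(log10(.data$p_predicted) - log10(.data$p))
    ) |>
    dplyr::rename(p_printed = "p")

  structure(
    list(
      m_hat = best$m, N_hat = best$N, variant_hat = best$variant,
      residual = sum(per_row$log10_residual^2),
      per_row = per_row,
      search = list(m_range = m_range, n_range = as.integer(n_range),
                    coarse_step = as.integer(coarse_step),
                    refine_window = as.integer(refine_window),
                    variants = variants, coarse_optimum = coarse)
    ),
    class = "ai_inversion"
  )
}

#' @export
print.ai_inversion <- function(x, ...) {
  cat("Enrichment background inversion\n")
  cat(sprintf("  m_hat = %d, N_hat = %d, variant = %s\n",
              x$m_hat, x$N_hat, x$variant_hat))
  cat(sprintf("  rows = %d, sum squared log10 residual = %.3g\n",
              nrow(x$per_row), x$residual))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-row predictions of an inversion fit
#'
#' @param x An `ai_inversion` object.
#' @param ... Unused.
#' @return Tibble with one row per input row: `n`, `k`, `p_printed`,
#'   `p_predicted`, `log10_residual`.
#' @method tidy ai_inversion
#' @export
tidy.ai_inversion <- function(x, ...) {
  x$per_row
}

#' One-row summary of an inversion fit
#'
#' @param x An `ai_inversion` object.
#' @param ... Unused.
#' @return One-row tibble: `m_hat`, `N_hat`, `variant_hat`, `residual`,
#'   `n_rows`, `max_log10_residual`.
#' @method glance ai_inversion
#' @export
glance.ai_inversion <- function(x, ...) {
  tibble::tibble(
    m_hat = x$m_hat, N_hat = x$N_hat, variant_hat = x$variant_hat,
    residual = x$residual, n_rows = nrow(x$per_row),
    max_log10_residual = max(x$per_row$log10_residual)
  )
}

#' Write an inversion report as TSV
#'
#' One line per input row (`row`, `n`, `k`, `p_printed`, `p_predicted`,
#' `abs_log10_residual`), followed by comment footer lines carrying the
#' recovered `m_hat`, `N_hat`, and `variant_hat`.
#'
#' @param inversion An `ai_inversion` object.
#' @param path File path.
#' @export
write_inversion_report <- function(inversion, path) {
  body <- inversion$per_row |>
    dplyr::mutate(row = dplyr::row_number()) |>
    dplyr::transmute(
      .data$row, .data$n, .data$k,
      p_printed = formatC(.data$p_printed, digits = 8, format = "g"),
      p_predicted = formatC(.data$p_predicted, digits = 8, format = "g"),
      abs_log10_residual = formatC(.data$log10_residual, digits = 4,
                                   format = "g")
    )
  lines <- c(
    paste(names(body), collapse = "\t"),
    do.call(paste, c(unname(as.list(body)), sep = "\t"))
  )
  writeLines(c(lines,
    paste0("# m_hat\t", inversion$m_hat),
    paste0("# N_hat\t", inversion$N_hat),
    paste0("# variant_hat\t", inversion$variant_hat),
    paste0("# residual\t", formatC(inversion$residual, digits = 6,
                                   format = "g"))
  ), path)
  invisible(path)
}

#' Exact-test table for planted background parameters
#'
#' Ground-truth generator for [invert_background()]: computes the exact-test
#' p-value for each `(n, k)` row under a named background `(m, N)` and
#' variant, yielding a table in the printed-results layout.
#'
#' @param m,N Planted disease-set and universe sizes.
#' @param variant Test variant, see [test_config()].
#' @param rows Data frame with columns `n` and `k`, all feasible under
#'   `(m, N)`.
#' @return Tibble with columns `n`, `k`, `p`.
#' @export
synth_inversion_table <- function(m, N, variant = "hypergeom_upper", rows) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0L) {
    return(tibble::tibble(n = integer(), k = integer(), p = numeric()))
  }
  n <- as.integer(rows$n); k <- as.integer(rows$k)
  if (any(n > N) || any(k > pmin(n, m))) {
    rlang::abort("infeasible (n, k) under the given (m, N)")
  }
  tibble::tibble(n = n, k = k, p = variant_fun(variant)(k, n, m, N))
}
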