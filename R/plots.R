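#' Plot an enrichment result
#'
#' Horizontal bar chart of the top results by `-log10(p)`, the usual
#' at-a-glance view of an over-representation screen.
#'
#' @param object An `ai_enrichment` tibble.
#' @param top_n Number of top-ranked rows to show.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @method autoplot ai_enrichment
#' @export
autoplot.ai_enrichment <- function(object, top_n = 20L, ...) {
  id_col <- if ("mirna" %in% names(object)) "mirna" else "term"
  df <- tibble::as_tibble(object) |>
    dplyr::slice_min(.data$rank, n = top_n) |>
    dplyr::mutate(id = stats::reorder(.data[[id_col]], -.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$id,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10](italic(p))), y = NULL,
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the distribution of miRNAs per disease gene
#'
#' Histogram of how many distinct miRNAs target each gene of the set,
#' including the zero class of genes with no reported miRNA association.
#'
#' @param counts Output of [mirna_counts_per_gene()].
#' @param binwidth Histogram bin width.
#' @return A `ggplot` object.
#' @export
plot_mirna_counts <- function(counts, binwidth = 5) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$n_mirnas)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "distinct miRNAs targeting the gene",
                  y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot an empirical power curve
#'
#' @param curve Output of [power_curve()].
#' @param alpha Nominal level drawn as a reference line.
#' @return A `ggplot` object.
#' @export
plot_power_curve <- function(curve, alpha = 0.05) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$boost, y = .data$power)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "overlap boost (log scale)", y = "empirical power") +
    ggplot2::theme_minimal()
}

#' Plot an inversion fit
#'
#' Predicted versus printed p-values on the log10 scale; points on the
#' diagonal are reproduced exactly by the recovered background.
#'
#' @param object An `ai_inversion` object.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @method autoplot ai_inversion
#' @export
autoplot.ai_inversion <- function(object, ...) {
  ggplot2::ggplot(object$per_row,
                  ggplot2::aes(x = log10(.data$p_printed),
                               y = log10(.data$p_predicted))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = expression(log[10](printed ~ italic(p))),
      y = expression(log[10](predicted ~ italic(p))),
      subtitle = sprintf("m = %d, N = %d, %s", object$m_hat, object$N_hat,
                         object$variant_hat)
    ) +
    ggplot2::theme_minimal()
}
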