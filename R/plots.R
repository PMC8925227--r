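# ggplot2 views of the result types.

#' Volcano plot of a differential-expression result
#'
#' @param x An `lnc_de` result from [exact_test_de()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_volcano <- function(x, ...) {
  crit <- attr(x, "criteria")
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)),
    colour = .data$de_flag
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "red", down = "green4", ns = "grey60")) +
    ggplot2::geom_hline(yintercept = -log10(crit[["max_padj"]]),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * crit[["min_abs_lfc"]],
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "log2 fold change (heat vs control)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.lnc_de <- function(object, ...) plot_volcano(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.lnc_structure_summary <- function(object, ...) {
  df <- object$exon_bins
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exon_bin, y = .data$fraction,
                                   fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "exon number", y = "fraction of transcripts",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of enrichment results
#'
#' @param enrichment Tibble from [hypergeom_enrich()].
#' @param top Terms per namespace to show (by p-value).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 15) {
  df <- enrichment %>%
    group_by(.data$namespace) %>%
    dplyr::slice_min(.data$pvalue, n = top, with_ties = FALSE) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$k / .data$n, y = stats::reorder(.data$term_id, -.data$pvalue),
    size = .data$k, colour = -log10(pmax(.data$pvalue, 1e-300))
  )) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~namespace, scales = "free_y") +
    ggplot2::labs(x = "gene ratio", y = NULL, colour = "-log10 p",
                  size = "genes") +
    ggplot2::theme_minimal()
}
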