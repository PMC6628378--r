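# ggplot2 visualisations.

#' Length distribution plot of clean reads
#'
#' @param object `mirdef_qc` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mirdef_qc <- function(object, ...) {
  ggplot2::ggplot(object$length_histogram,
                  ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "insert length (nt)", y = "clean reads",
                  title = "Clean read length distribution") +
    ggplot2::theme_minimal()
}

#' MA plot of a differential-expression result
#'
#' @param object `mirdef_de` object.
#' @param comparison comparison label to show (default: the first one).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mirdef_de <- function(object, comparison = NULL, ...) {
  d <- as_tibble(object)
  comparison <- comparison %||% d$comparison[1]
  d <- filter(d, .data$comparison == !!comparison)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$A, y = .data$M,
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "navy", ns = "grey60")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(title = paste("MA plot:", comparison),
                  x = "A (mean log2 count)", y = "M (log2 ratio)") +
    ggplot2::theme_minimal()
}

#' Fold-change heatmap in clustered order
#'
#' @param object `mirdef_cluster` object from [cluster_order()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mirdef_cluster <- function(object, ...) {
  long <- as_tibble(object$matrix, rownames = "mirna") %>%
    tidyr::pivot_longer(-"mirna", names_to = "comparison",
                        values_to = "log2fc") %>%
    mutate(mirna = factor(.data$mirna, levels = object$row_order),
           comparison = factor(.data$comparison, levels = object$col_order))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$comparison, y = .data$mirna,
                                     fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Enrichment dot plot
#'
#' @param object `mirdef_enrich` object.
#' @param top terms shown per namespace (default 10).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mirdef_enrich <- function(object, top = 10, ...) {
  d <- as_tibble(object) %>%
    group_by(.data$namespace) %>%
    slice(seq_len(min(top, n()))) %>%
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p),
                                  y = stats::reorder(.data$term_name, -.data$p),
                                  size = .data$k, colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~.data$namespace, scales = "free_y") +
    ggplot2::labs(x = "-log10 p", y = NULL) +
    ggplot2::theme_minimal()
}
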