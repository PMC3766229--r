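#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_segment
#'   geom_text labs theme_minimal scale_fill_manual facet_wrap
#' @export
ggplot2::autoplot

BASE_COLOURS <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")

#' Simplified sequence-logo plot of a PSSM
#'
#' Stacked per-column bars whose heights are base frequency times column
#' information content, with the base letter printed on each segment - a
#' logo-style summary without glyph scaling.
#'
#' @param object A [pssm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pssm <- function(object, ...) {
  d <- tidy(object) |>
    mutate(height = .data$frequency * .data$information_bits) |>
    filter(.data$height > 0.01)
  ggplot(d, aes(x = .data$position, y = .data$height, fill = .data$base)) +
    geom_col(width = 0.85, colour = "white", linewidth = 0.2) +
    geom_text(aes(label = .data$base),
              position = ggplot2::position_stack(vjust = 0.5),
              colour = "white", size = 3, fontface = "bold") +
    scale_fill_manual(values = BASE_COLOURS, guide = "none") +
    labs(title = object$name, x = "position", y = "bits") +
    theme_minimal()
}

#' Plot a bipartite regulatory network
#'
#' Motifs on the left, genes on the right (coloured by category), one
#' segment per motif-gene edge.
#'
#' @param object A `regulatory_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regulatory_network <- function(object, ...) {
  motifs <- object$motifs |>
    mutate(x = 0, y = seq_len(dplyr::n()), label = .data$motif)
  genes <- object$genes |>
    mutate(x = 1,
           y = seq(1, max(nrow(object$motifs), dplyr::n()),
                   length.out = max(dplyr::n(), 1)),
           label = .data$gene_id)
  edges <- object$edges |>
    left_join(select(motifs, motif = "motif", x0 = "x", y0 = "y"), by = "motif") |>
    left_join(select(genes, gene_id = "gene_id", x1 = "x", y1 = "y"),
              by = "gene_id")
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                     yend = .data$y1, linewidth = .data$n_occurrences),
                 colour = "grey60", alpha = 0.6) +
    geom_point(data = motifs, aes(x = .data$x, y = .data$y), shape = 15,
               size = 3, colour = "grey20") +
    geom_point(data = genes, aes(x = .data$x, y = .data$y,
                                 colour = .data$category), size = 3) +
    geom_text(data = motifs, aes(x = .data$x - 0.05, y = .data$y,
                                 label = .data$label), hjust = 1, size = 3) +
    geom_text(data = genes, aes(x = .data$x + 0.05, y = .data$y,
                                label = .data$label), hjust = 0, size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5), guide = "none") +
    ggplot2::xlim(-0.5, 1.5) +
    labs(x = NULL, y = NULL, colour = "category") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Score-report overview plot
#'
#' Church score against ROC-AUC for every scored motif, with the filter
#' thresholds drawn and retained motifs highlighted.
#'
#' @param reports Output of [filter_cascade()].
#' @param config The [filter_config()] used (for threshold lines).
#' @return A ggplot object.
#' @export
plot_score_reports <- function(reports, config = filter_config()) {
  ggplot(reports, aes(x = .data$roc_auc, y = -log10(pmax(.data$church_p, 1e-16)),
                      colour = .data$retained)) +
    geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = config$roc_auc_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(config$church_max), linetype = 2) +
    labs(x = "ROC-AUC", y = "-log10 Church score", colour = "retained") +
    theme_minimal()
}
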