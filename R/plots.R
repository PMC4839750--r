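# ggplot2 views of the main result types.

#' Plot the distribution of active-time-point counts
#'
#' Bar chart of how many proteins are active at 0, 1, 2, ... time points.
#'
#' @param schedule Activity schedule ([activity_profiles()]).
#' @return A ggplot object.
#' @export
plot_activity_histogram <- function(schedule) {
  h <- activity_histogram(schedule)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$n_active, y = .data$n_proteins)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Number of active time points",
                  y = "Number of proteins") +
    ggplot2::theme_minimal()
}

#' @describeIn network_properties Autoplot method: node/edge counts and
#'   density over time for a `tepin`.
#' @param object A `tepin`.
#' @param ... Unused.
#' @export
autoplot.tepin <- function(object, ...) {
  p <- network_properties(object)
  p <- p[p$snapshot != "average", , drop = FALSE]
  p$timepoint <- seq_len(nrow(p))
  long <- tidyr::pivot_longer(p[c("timepoint", "n_nodes", "n_edges", "density")],
                              -"timepoint", names_to = "property")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~property, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Time point", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot enrichment p-value bins
#'
#' @param annotated Output of [annotate_complexes()].
#' @return A ggplot object.
#' @export
plot_enrichment_bins <- function(annotated) {
  b <- enrichment_bins(annotated)
  b$bin <- factor(b$bin, levels = enrichment_bin_labels)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$bin, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Best p-value interval", y = "% of predicted complexes") +
    ggplot2::theme_minimal()
}
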