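#' Density of population-graph edge values
#'
#' Kernel density of the off-diagonal (lower-triangle) values of a
#' population graph — the standard diagnostic for comparing PSG/POG value
#' distributions across modalities and omics types.
#'
#' @param object A `population_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot population_graph
#' @export
autoplot.population_graph <- function(object, ...) {
  vals <- object$adjacency[lower.tri(object$adjacency)]
  df <- tibble::tibble(value = vals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(
      x = sprintf("%s edge weight", object$kind),
      y = "density",
      title = sprintf("%s edge-weight distribution (%d scans)",
                      object$kind, nrow(object$adjacency))
    ) +
    ggplot2::theme_minimal()
}

#' Compare edge-value distributions across several population graphs
#'
#' @param graphs Named list of `population_graph` objects.
#' @return A ggplot object with one density per graph.
#' @export
plot_graph_densities <- function(graphs) {
  df <- dplyr::bind_rows(lapply(names(graphs), function(nm) {
    a <- graphs[[nm]]$adjacency
    tibble::tibble(graph = nm, value = a[lower.tri(a)])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$graph)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "edge weight", y = "density") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-class attention weights
#'
#' Displays the omics-by-class attention matrices from
#' [attention_report()]: one panel per predicted class, omics types on the
#' x axis, class logits on the y axis.
#'
#' @param report A tibble from [attention_report()] (or the pooled
#'   `attention` column of a protocol result).
#' @return A ggplot object.
#' @export
plot_attention <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$omics,
                                       y = factor(.data$class_logit),
                                       fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$weight)),
                       colour = "white") +
    ggplot2::facet_wrap(~ .data$predicted_class,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "omics network", y = "class logit",
                  fill = "attention") +
    ggplot2::theme_minimal()
}

#' Training curves of a fitted model
#'
#' @param object A `joingcla_fit`.
#' @param ... Unused.
#' @return A ggplot object: loss, training MCC and validation MCC by epoch.
#' @method autoplot joingcla_fit
#' @export
autoplot.joingcla_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "metric", values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
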