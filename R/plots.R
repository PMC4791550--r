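#' Plot a gene regulatory network
#'
#' Force-directed layout (deterministic, seeded) with node size proportional
#' to out-degree — the hub-emphasis rendering — and color by hierarchy
#' class.
#'
#' @param object A `gene_network`.
#' @param label_top Label the `label_top` highest-ranked hubs (0 for none).
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_network
#' @export
autoplot.gene_network <- function(object, label_top = 5L, seed = 1L, ...) {
  g <- to_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tidy.gene_network(object)
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  arcs <- object$arcs |>
    dplyr::left_join(nodes[c("gene", "x", "y")], by = c(from = "gene")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes[c("gene", "x", "y")], by = c(to = "gene"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = arcs,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y),
      linewidth = 0.3, color = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(1.6, "mm"))) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$out_degree,
                   color = .data$hierarchy_class)) +
    ggplot2::scale_size_continuous(range = c(1.5, 8)) +
    ggplot2::labs(size = "out-degree", color = "class") +
    ggplot2::theme_void()
  if (label_top > 0) {
    lab <- dplyr::filter(nodes, .data$hub_rank <= label_top, .data$out_degree > 0)
    p <- p + ggplot2::geom_text(
      data = lab, ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
      vjust = -1, size = 3)
  }
  p
}

#' Plot trajectories as state step functions
#'
#' @param object A `ctbn_trajectory` tibble.
#' @param variables Variables to show (default: all).
#' @param ... Unused.
#' @return A ggplot with one facet per variable, one line per trajectory.
#' @method autoplot ctbn_trajectory
#' @export
autoplot.ctbn_trajectory <- function(object, variables = NULL, ...) {
  vars <- variables %||% trajectory_variables(object)
  long <- tibble::as_tibble(object) |>
    dplyr::select("trajectory_id", "t_start", dplyr::all_of(vars)) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable",
                        values_to = "state")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_start, y = .data$state,
                                     group = .data$trajectory_id,
                                     color = factor(.data$trajectory_id))) +
    ggplot2::geom_step(alpha = 0.7) +
    ggplot2::facet_wrap(~variable) +
    ggplot2::labs(x = "time (h)", y = "state", color = "trajectory") +
    ggplot2::theme_minimal()
}

#' Selection plot: effect size versus significance
#'
#' One point per gene: maximum absolute replicate-mean log2 fold change over
#' time against the smallest BH-adjusted p-value, with the selection
#' thresholds drawn.
#'
#' @param fc Output of [fold_change()].
#' @param de Output of [differential_expression()].
#' @param config A [selection_config()] (for threshold lines).
#' @return A ggplot object.
#' @export
plot_selection <- function(fc, de, config = selection_config()) {
  mean_fc <- fc |>
    dplyr::summarise(mfc = mean(.data$fc), .by = c("gene", "time_h"))
  per_gene <- dplyr::inner_join(mean_fc, de, by = c("gene", "time_h")) |>
    dplyr::summarise(max_abs_fc = max(abs(.data$mfc)),
                     min_q = min(.data$q), .by = "gene") |>
    dplyr::mutate(selected = .data$gene %in% select_genes(fc, de, config)$gene)
  ggplot2::ggplot(per_gene,
                  ggplot2::aes(x = .data$max_abs_fc,
                               y = -log10(pmax(.data$min_q, 1e-300)),
                               color = .data$selected)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = config$fc_abs_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(config$de_alpha), linetype = 2) +
    ggplot2::labs(x = "max |log2 fold change|", y = "-log10 min q",
                  color = "selected") +
    ggplot2::theme_minimal()
}
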