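# ggplot2 displays for the main result types.

#' Plot efficiency and cost-efficiency curves
#'
#' @param object A `basc_cost_curve` from [cost_scan()].
#' @param ... Unused.
#' @return A ggplot: global efficiency and cost efficiency against cost,
#'   with the cost-efficiency argmax marked.
#' @method autoplot basc_cost_curve
#' @export
autoplot.basc_cost_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("cost", "global_efficiency", "cost_efficiency")],
    -"cost", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cost, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "argmax_cost"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "cost (fraction of edges)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a stability matrix
#'
#' @param stability A `basc_stability` (or plain matrix in `[0, 1]`).
#' @param order_by Optional `basc_partition` used to order regions by
#'   cluster.
#' @return A ggplot tile heatmap.
#' @export
plot_stability_matrix <- function(stability, order_by = NULL) {
  S <- if (inherits(stability, "basc_stability")) stability$values else stability
  ord <- if (!is.null(order_by)) order(order_by$labels) else seq_len(nrow(S))
  S <- S[ord, ord]
  df <- tibble(
    i = rep(seq_len(nrow(S)), times = ncol(S)),
    j = rep(seq_len(ncol(S)), each = nrow(S)),
    stability = as.vector(S)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$stability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "stability") +
    ggplot2::theme_minimal()
}

#' Group means of a node metric per cluster
#'
#' Bar chart of per-cluster group means with SD error bars, restricted to
#' the hub analysis set when a report is supplied.
#'
#' @param metrics Tibble from [cohort_node_metrics()].
#' @param hubs Optional `basc_hub_report`; restricts the clusters shown and
#'   draws the hub rule threshold.
#' @param metric Metric column (default `degree_avg`).
#' @return A ggplot.
#' @export
plot_group_degree <- function(metrics, hubs = NULL, metric = "degree_avg") {
  d <- metrics
  if (!is.null(hubs)) d <- filter(d, .data$cluster %in% hubs$analysis_set)
  summ <- d |>
    group_by(.data$cluster, .data$group) |>
    summarise(m = mean(.data[[metric]]), s = sd(.data[[metric]]),
              .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$cluster),
                                          y = .data$m, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$s, ymax = .data$m + .data$s),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = "cluster", y = metric, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(hubs)) {
    p <- p + ggplot2::geom_hline(yintercept = hubs$rule_mean + hubs$rule_sd,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
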