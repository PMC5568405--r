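#' Plot a swarm trajectory
#'
#' Agent paths in the x-y plane (3-D runs are projected) with the group
#' centroid drawn as a thick red line — the line whose shape distinguishes
#' straight, helical and orbiting collective motions at a glance.
#'
#' @param object A `swarm_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swarm_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$states,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               group = .data$agent_id)) +
    ggplot2::geom_path(alpha = 0.35, linewidth = 0.3) +
    ggplot2::geom_path(data = object$centroid,
                       ggplot2::aes(group = NULL),
                       color = "red", linewidth = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y",
                  title = sprintf("N = %d, K = %d", object$n, object$k)) +
    ggplot2::theme_minimal()
}

#' Plot network-metric time series
#'
#' One facet per metric, over simulation steps.
#'
#' @param metrics A [metrics_timeseries()] tibble.
#' @return A ggplot object.
#' @export
plot_metrics_timeseries <- function(metrics) {
  long <- tidyr::pivot_longer(
    dplyr::select(metrics, "step", "density", "entropy", "avg_geodesic",
                  "avg_clustering", "n_components"),
    -"step", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot an out-degree distribution
#'
#' @param graph A directed interaction graph.
#' @return A ggplot object.
#' @export
plot_out_degrees <- function(graph) {
  dd <- out_degree_distribution(graph)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$out_degree,
                                   y = .data$n_agents)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "out-degree", y = "agents") +
    ggplot2::theme_minimal()
}
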