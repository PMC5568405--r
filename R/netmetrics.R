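#' Network density of a directed graph
#'
#' Edge count over `N * (N - 1)`. For any K-nearest-neighbor interaction
#' graph this equals `K / (N - 1)` exactly and stays constant for the whole
#' run, since every agent always perceives exactly K others.
#'
#' @inheritParams out_degree_distribution
#' @return A single number in `[0, 1]`.
#' @export
graph_density <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2) stop("density is undefined for fewer than 2 agents", call. = FALSE)
  igraph::ecount(graph) / (n * (n - 1))
}

#' Network entropy of the out-degree distribution
#'
#' Shannon entropy (natural log) of the distribution of out-degrees:
#' `-sum(p_k * log(p_k))` where `p_k` is the fraction of agents with
#' out-degree `k`. Zero exactly when all out-degrees are equal, as in the
#' degree-regular graph obtained at `K = N - 1`.
#'
#' @inheritParams out_degree_distribution
#' @return Entropy in nats (>= 0).
#' @export
network_entropy <- function(graph) {
  deg <- igraph::degree(graph, mode = "out")
  p <- as.numeric(table(deg)) / length(deg)
  # + 0 normalizes the -0 produced by a degenerate distribution
  -sum(p * log(p)) + 0
}

#' Average geodesic distance over reachable pairs
#'
#' Mean directed shortest-path length (in hops) over all ordered pairs
#' `(i, j)`, `i != j`, that are reachable; unreachable pairs (infinite
#' geodesic distance, e.g. across fission subgroups) are excluded from the
#' mean and reported through `reachable_pair_fraction`.
#'
#' @inheritParams out_degree_distribution
#' @return A one-row tibble with `avg_geodesic` and
#'   `reachable_pair_fraction`.
#' @export
network_geodesic <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2) stop("geodesic distance is undefined for fewer than 2 agents",
                  call. = FALSE)
  d <- igraph::distances(graph, mode = "out")
  d <- d[row(d) != col(d)]
  reachable <- is.finite(d)
  if (!any(reachable)) stop("no reachable ordered pair", call. = FALSE)
  tibble::tibble(avg_geodesic = mean(d[reachable]),
                 reachable_pair_fraction = mean(reachable))
}

#' Average clustering coefficient
#'
#' Mean of the local (Watts-Strogatz) clustering coefficients computed on
#' the undirected projection of the graph (an undirected edge exists
#' whenever either directed edge does). Vertices with fewer than two
#' neighbors contribute 0.
#'
#' @inheritParams out_degree_distribution
#' @return A single number in `[0, 1]`.
#' @export
network_clustering <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 3) stop("clustering is undefined for fewer than 3 agents",
                  call. = FALSE)
  u <- igraph::as_undirected(graph, mode = "collapse")
  cc <- igraph::transitivity(u, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  mean(cc)
}

#' All network metrics of one interaction graph
#'
#' @inheritParams out_degree_distribution
#' @return A one-row tibble: `step` (if recorded on the graph), `density`,
#'   `entropy`, `avg_geodesic`, `avg_clustering`,
#'   `reachable_pair_fraction`, `n_components` (weak components). Metrics
#'   undefined at the graph's size are `NA`.
#' @export
network_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  step <- igraph::graph_attr(graph, "step")
  geo <- if (n >= 2 && igraph::ecount(graph) > 0) {
    network_geodesic(graph)
  } else {
    tibble::tibble(avg_geodesic = NA_real_, reachable_pair_fraction = 0)
  }
  tibble::tibble(
    step = if (is.null(step)) NA_integer_ else as.integer(step),
    density = if (n >= 2) graph_density(graph) else NA_real_,
    entropy = network_entropy(graph),
    avg_geodesic = geo$avg_geodesic,
    avg_clustering = if (n >= 3) network_clustering(graph) else NA_real_,
    reachable_pair_fraction = geo$reachable_pair_fraction,
    n_components = igraph::components(graph, mode = "weak")$no
  )
}

#' Network metrics along a trajectory
#'
#' Rebuilds the interaction graph at stored snapshots and evaluates all
#' network metrics, yielding the metric time series whose convergence (or
#' jump at the fission critical point) summarises the run.
#'
#' @param trajectory A [run_swarm()] result.
#' @param stride Keep every `stride`-th stored snapshot (>= 1). Snapshots
#'   are already thinned by the run's own stride; this thins further.
#' @return A tibble with one row per evaluated snapshot (columns as
#'   [network_metrics()]).
#' @export
metrics_timeseries <- function(trajectory, stride = 1) {
  stopifnot(inherits(trajectory, "swarm_trajectory"))
  stride <- check_count(stride, "stride")
  steps <- unique(trajectory$states$step)
  steps <- steps[seq(1, length(steps), by = stride)]
  purrr::map_dfr(steps, function(s) {
    pos <- dplyr::filter(trajectory$states, .data$step == s)
    network_metrics(interaction_graph(pos, trajectory$k, step = s))
  })
}
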