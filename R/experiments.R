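#' Run one complete experiment
#'
#' Generates (or takes) an initial configuration, runs the simulation,
#' computes the network-metric time series and the behavior report, and
#' optionally writes all artifacts to a run directory: `trajectory.csv`,
#' `metrics.csv`, `behavior.json`, `summary.json`, and the final graph as
#' `network_final.edgelist`. The summary embeds the full parameter set and
#' seed, so identical summaries imply identical runs.
#'
#' @param n Number of agents (ignored when `init` is given).
#' @param k Number of perceived neighbors.
#' @param seed Scenario RNG seed.
#' @param params A [swarm_params()].
#' @param scenario Initial-condition family, see [generate_scenario()].
#' @param scenario_args Extra arguments for the scenario generator.
#' @param init Optional explicit initial positions tibble (overrides
#'   `scenario`).
#' @param stride Snapshot stride for [run_swarm()].
#' @param metrics_stride Further thinning for the metric time series
#'   (in stored snapshots).
#' @param thresholds A [motion_thresholds()].
#' @param out_dir Optional output directory (created if missing).
#' @return A list with `trajectory`, `metrics`, `behavior`, and a one-row
#'   `summary` tibble.
#' @export
run_experiment <- function(n, k, seed = 1L, params = swarm_params(),
                           scenario = "uniform_cloud",
                           scenario_args = list(), init = NULL,
                           stride = 10, metrics_stride = 10,
                           thresholds = motion_thresholds(),
                           out_dir = NULL) {
  if (is.null(init)) {
    init <- do.call(generate_scenario,
                    c(list(kind = scenario, n = n, dims = params$dims,
                           seed = seed), scenario_args))
  }
  traj <- run_swarm(init, k, params, stride = stride)
  metrics <- metrics_timeseries(traj, stride = metrics_stride)
  behavior <- classify_motion(traj, thresholds)

  summary <- dplyr::bind_cols(
    tibble::tibble(seed = as.integer(seed), scenario = scenario),
    tidy(behavior),
    dplyr::select(metrics[nrow(metrics), ],
                  final_density = "density", final_entropy = "entropy",
                  final_geodesic = "avg_geodesic",
                  final_clustering = "avg_clustering",
                  final_reachable = "reachable_pair_fraction",
                  final_components = "n_components")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    write_behavior_json(behavior, file.path(out_dir, "behavior.json"))
    g <- interaction_graph(final_state(traj), k, step = traj$n_steps)
    write_graph_snapshot(g, file.path(out_dir, "network_final.edgelist"))
    jsonlite::write_json(
      c(as.list(summary), list(params = unclass(params),
                               package_version =
                                 as.character(utils::packageVersion("toposwarm")))),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, na = "null",
      digits = NA)
  }
  list(trajectory = traj, metrics = metrics, behavior = behavior,
       summary = summary)
}

# one sweep cell: classify a single run without keeping the trajectory
classify_cell <- function(n, k, seed, params, stride, thresholds, scenario,
                          scenario_args = list()) {
  init <- do.call(generate_scenario,
                  c(list(kind = scenario, n = n, dims = params$dims,
                         seed = seed), scenario_args))
  traj <- run_swarm(init, k, params, stride = stride)
  g <- interaction_graph(final_state(traj), k)
  met <- network_metrics(g)
  dplyr::bind_cols(
    tibble::tibble(seed = as.integer(seed)),
    tidy(classify_motion(traj, thresholds)),
    dplyr::select(met, density = "density", entropy = "entropy",
                  avg_geodesic = "avg_geodesic",
                  avg_clustering = "avg_clustering",
                  n_components = "n_components")
  )
}

#' Sweep group size and neighbor count
#'
#' Runs every `(n, k, seed)` cell with `k < n`, classifies each run, and
#' returns one row per cell. Per-cell failures (e.g. numerical blow-up)
#' are recorded in the `status` column and do not stop the sweep.
#'
#' @param n_values,k_values Integer vectors of group sizes and neighbor
#'   counts; cells with `k >= n` are skipped.
#' @param seeds Integer vector of scenario seeds run per cell.
#' @param params A [swarm_params()].
#' @param scenario Initial-condition family.
#' @param stride Snapshot stride passed to [run_swarm()].
#' @param thresholds A [motion_thresholds()].
#' @param progress Print one line per cell.
#' @return A tibble keyed by (`n`, `k`, `seed`) with the behavior and
#'   final network metrics of every run, plus `status` (`"ok"` or the
#'   error message).
#' @export
sweep_nk <- function(n_values, k_values, seeds = 1:5,
                     params = swarm_params(), scenario = "uniform_cloud",
                     stride = 10, thresholds = motion_thresholds(),
                     progress = FALSE) {
  cells <- tidyr::expand_grid(n = as.integer(n_values),
                              k = as.integer(k_values),
                              seed = as.integer(seeds))
  cells <- dplyr::filter(cells, .data$k < .data$n, .data$k >= 0)
  purrr::pmap_dfr(cells, function(n, k, seed) {
    if (progress) message(sprintf("n=%d k=%d seed=%d", n, k, seed))
    tryCatch(
      dplyr::mutate(classify_cell(n, k, seed, params, stride, thresholds,
                                  scenario),
                    status = "ok"),
      error = function(e) {
        tibble::tibble(seed = as.integer(seed), n = n, k = k,
                       motion_type = NA_character_, status = conditionMessage(e))
      }
    )
  })
}

#' Summarise the fission region of a sweep
#'
#' A cell `(n, k)` belongs to the fission region when at least one of its
#' seeds produced sustained fission. Reports the K/N ratio statistics over
#' the region (as percentages) together with the smallest fissioning `k`.
#'
#' @param sweep A [sweep_nk()] result.
#' @return A one-row tibble: `n_cells`, `min_k`, `min_kn_pct`,
#'   `max_kn_pct`, `mean_kn_pct`. All `NA` when no cell fissions.
#' @export
fission_summary <- function(sweep) {
  cells <- sweep |>
    dplyr::group_by(.data$n, .data$k) |>
    dplyr::summarise(
      fission = any(.data$motion_type == "fission", na.rm = TRUE),
      .groups = "drop") |>
    dplyr::filter(.data$fission)
  if (nrow(cells) == 0) {
    return(tibble::tibble(n_cells = 0L, min_k = NA_integer_,
                          min_kn_pct = NA_real_, max_kn_pct = NA_real_,
                          mean_kn_pct = NA_real_))
  }
  kn <- 100 * cells$k / cells$n
  tibble::tibble(n_cells = nrow(cells), min_k = min(cells$k),
                 min_kn_pct = min(kn), max_kn_pct = max(kn),
                 mean_kn_pct = mean(kn))
}

#' Smallest K at which collective motion emerges
#'
#' Scans `k` upward at fixed group size and reports the smallest `k` for
#' which a majority of seeds classify as a coherent collective type (types
#' 1-7; disorder and fission do not count). Majority voting over seeds
#' stands in for the single unpublished initial configuration of the
#' reference simulations.
#'
#' @param n Group size.
#' @param k_max Largest `k` scanned (default `min(10, n - 1)`).
#' @param seeds Scenario seeds voted over.
#' @param params A [swarm_params()].
#' @param stride Snapshot stride.
#' @param thresholds A [motion_thresholds()].
#' @param scenario Initial-condition family.
#' @return A one-row tibble with `n`, `threshold_k` (`NA` if no scanned
#'   `k` wins a majority), and `votes` (list-column: per-k collective
#'   vote counts).
#' @export
emergence_threshold <- function(n, k_max = min(10, n - 1), seeds = 1:10,
                                params = swarm_params(), stride = 10,
                                thresholds = motion_thresholds(),
                                scenario = "uniform_cloud") {
  n <- check_count(n, "n", min = 2)
  k_max <- check_count(k_max, "k_max")
  if (k_max > n - 1) stop("k_max must be at most n - 1", call. = FALSE)
  votes <- tibble::tibble(k = integer(), collective = integer(),
                          total = integer())
  threshold <- NA_integer_
  for (k in seq_len(k_max)) {
    types <- vapply(seeds, function(s) {
      tryCatch(classify_cell(n, k, s, params, stride, thresholds,
                             scenario)$motion_type,
               error = function(e) NA_character_)
    }, character(1))
    coll <- sum(types %in% as.character(1:7), na.rm = TRUE)
    votes <- dplyr::bind_rows(votes,
                              tibble::tibble(k = k, collective = coll,
                                             total = length(seeds)))
    if (is.na(threshold) && coll > length(seeds) / 2) {
      threshold <- as.integer(k)
      break
    }
  }
  tibble::tibble(n = as.integer(n), threshold_k = threshold,
                 votes = list(votes))
}
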