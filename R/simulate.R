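#' Run the swarm simulation
#'
#' Iterates the synchronous first-order update from an initial
#' configuration until `t_max` steps or until the relative configuration
#' becomes stationary: the largest per-step change of any pairwise distance
#' stays below `stability_tol * d_e` for `stability_window` consecutive
#' steps. Stationarity is defined on pairwise distances, not absolute
#' positions, so a rigidly translating or rotating group still counts as
#' stable. Space is unbounded and the dynamics are deterministic given the
#' initial state.
#'
#' Agent snapshots are stored every `stride` steps (plus the first and last
#' step); the centroid path, the weak-component count of the interaction
#' graph, the mean nearest-neighbor distance and the maximum pairwise
#' distance change are recorded at every step.
#'
#' @inheritParams interaction_forces
#' @param stride Snapshot thinning interval in steps (>= 1).
#' @return A `swarm_trajectory` object: list with `states` (long tibble
#'   `step`, `agent_id`, `x`, `y`\[, `z`\]), `centroid` (per-step tibble),
#'   `series` (per-step tibble `step`, `n_components`, `mean_nn_dist`,
#'   `max_dist_change`), `params`, `k`, `n`, `dims`, `stride`, `n_steps`,
#'   and `stationary_at` (`NA` if stationarity was never sustained).
#' @examples
#' pos <- tibble::tibble(agent_id = 0:1, x = c(0, 6), y = 0, z = 0)
#' traj <- run_swarm(pos, k = 1, params = swarm_params(t_max = 2000))
#' glance(traj)
#' @export
run_swarm <- function(positions, k, params = swarm_params(), stride = 10) {
  stopifnot(inherits(params, "swarm_params"))
  m <- position_matrix(positions)
  n <- nrow(m)
  k <- check_count(k, "k", min = 0)
  if (k > n - 1) {
    stop("k must be at most N - 1 (got k = ", k, ", N = ", n, ")",
         call. = FALSE)
  }
  if (ncol(m) != params$dims) {
    stop("positions are ", ncol(m), "-dimensional but params$dims = ",
         params$dims, call. = FALSE)
  }
  stride <- check_count(stride, "stride")

  res <- .simulate_swarm_cpp(m, k, params$d_l, params$d_e, params$d_h,
                             params$k1, params$k2, params$k3,
                             params$a, params$b, params$c,
                             params$t_max, params$stability_tol,
                             params$stability_window, stride)
  if (res$status == 1L) {
    stop("degenerate geometry: coincident agents among neighbors at step ",
         res$error_step, call. = FALSE)
  }
  if (res$status == 2L) {
    stop("numerical blow-up: non-finite coordinates at step ",
         res$error_step, call. = FALSE)
  }

  ids <- as.integer(rownames(m))
  n_steps <- res$n_steps
  keep <- seq_len(n_steps + 1)
  dims <- ncol(m)

  snap_mat <- do.call(rbind, res$snapshots)
  states <- dplyr::bind_cols(
    tibble::tibble(step = rep(as.integer(res$snapshot_steps), each = n),
                   agent_id = rep(ids, times = length(res$snapshot_steps))),
    tibble::as_tibble(setNames(as.data.frame(snap_mat), coord_names(dims)))
  )

  centroid <- tibble::as_tibble(setNames(
    as.data.frame(res$centroid[keep, , drop = FALSE]), coord_names(dims)))
  centroid <- dplyr::bind_cols(tibble::tibble(step = 0:n_steps), centroid)

  series <- tibble::tibble(
    step = 0:n_steps,
    n_components = res$n_components[keep],
    mean_nn_dist = res$mean_nn_dist[keep],
    max_dist_change = res$max_dist_change[keep]
  )

  structure(
    list(states = states, centroid = centroid, series = series,
         params = params, k = k, n = n, dims = dims, stride = stride,
         n_steps = n_steps,
         stationary_at = if (res$stationary_at < 0) NA_integer_
                         else as.integer(res$stationary_at)),
    class = "swarm_trajectory"
  )
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  cat(sprintf("<swarm_trajectory> N=%d K=%d dims=%d, %d steps (%d snapshots)\n",
              x$n, x$k, x$dims, x$n_steps, length(unique(x$states$step))))
  if (is.na(x$stationary_at)) {
    cat("  stationarity: not reached\n")
  } else {
    cat(sprintf("  stationarity: sustained from step %d\n", x$stationary_at))
  }
  invisible(x)
}

#' Tidy a swarm trajectory into its long state table
#'
#' @param x A `swarm_trajectory`.
#' @param ... Unused.
#' @return The long tibble of stored states (`step`, `agent_id`,
#'   coordinates).
#' @export
tidy.swarm_trajectory <- function(x, ...) x$states

#' One-row summary of a swarm trajectory
#'
#' @param x A `swarm_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `k`, `dims`, `n_steps`, `stationary_at`,
#'   final `n_components` and `mean_nn_dist`, and the final centroid speed
#'   (length of the last per-step centroid displacement).
#' @export
glance.swarm_trajectory <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, dims = x$dims, n_steps = x$n_steps,
    stationary_at = x$stationary_at,
    n_components = tail(x$series$n_components, 1),
    mean_nn_dist = tail(x$series$mean_nn_dist, 1),
    centroid_speed = final_centroid_speed(x)
  )
}

# length of the last centroid displacement (0 for a single-state trajectory)
final_centroid_speed <- function(trajectory) {
  cp <- as.matrix(trajectory$centroid[, -1, drop = FALSE])
  if (nrow(cp) < 2) return(0)
  sqrt(sum((cp[nrow(cp), ] - cp[nrow(cp) - 1, ])^2))
}

#' Final stored state of a trajectory
#'
#' @param trajectory A `swarm_trajectory`.
#' @return The positions tibble of the last stored snapshot, with its step
#'   index in the `step` attribute.
#' @export
final_positions <- function(trajectory) {
  stopifnot(inherits(trajectory, "swarm_trajectory"))
  s <- max(trajectory$states$step)
  out <- dplyr::filter(trajectory$states, .data$step == s)
  out <- dplyr::select(out, -"step")
  attr(out, "step") <- s
  out
}

# internal alias used throughout
final_state <- function(trajectory) final_positions(trajectory)
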