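# default analysis window: last `frac` of the trajectory's steps
default_window <- function(trajectory, frac = 0.25) {
  c(floor((1 - frac) * trajectory$n_steps), trajectory$n_steps)
}

check_window <- function(trajectory, window) {
  if (is.null(window)) window <- default_window(trajectory)
  stopifnot(length(window) == 2, window[1] <= window[2])
  window <- as.integer(pmax(0, pmin(window, trajectory$n_steps)))
  window
}

#' Straightness of the group path
#'
#' Chord-over-arc ratio of the centroid path inside the analysis window:
#' the net centroid displacement divided by the total centroid path length.
#' Equals 1 for perfectly straight motion and approaches 0 for closed
#' orbits. Invariant under translation, rotation and uniform rescaling of
#' the trajectory. Computed on the full-resolution centroid path.
#'
#' @param trajectory A [run_swarm()] result.
#' @param window Integer step interval `c(from, to)`; default the last 25%
#'   of steps, skipping the initial transient.
#' @return A number in `[0, 1]`. If the centroid never moves inside the
#'   window the value is 0 and carries attribute `stationary = TRUE`.
#' @export
straightness <- function(trajectory, window = NULL) {
  stopifnot(inherits(trajectory, "swarm_trajectory"))
  window <- check_window(trajectory, window)
  cp <- dplyr::filter(trajectory$centroid,
                      .data$step >= window[1], .data$step <= window[2])
  cp <- as.matrix(cp[, -1, drop = FALSE])
  if (nrow(cp) < 2) stop("window must contain at least 2 steps", call. = FALSE)
  seg <- diff(cp)
  arc <- sum(sqrt(rowSums(seg^2)))
  if (arc == 0) {
    return(structure(0, stationary = TRUE))
  }
  chord <- sqrt(sum((cp[nrow(cp), ] - cp[1, ])^2))
  min(1, chord / arc)
}

# cross-product magnitude helper: rows of r x rows of v
cross_sum_norm <- function(r, v) {
  if (ncol(r) == 2) {
    abs(sum(r[, 1] * v[, 2] - r[, 2] * v[, 1]))
  } else {
    cx <- sum(r[, 2] * v[, 3] - r[, 3] * v[, 2])
    cy <- sum(r[, 3] * v[, 1] - r[, 1] * v[, 3])
    cz <- sum(r[, 1] * v[, 2] - r[, 2] * v[, 1])
    sqrt(cx^2 + cy^2 + cz^2)
  }
}

#' Helicity of the group motion
#'
#' Time-averaged normalized group angular momentum about the instantaneous
#' centroid: at each stored snapshot transition,
#' `|sum_i r_i x v_i| / sum_i |r_i| |v_i|`, with `r_i` the agent position
#' relative to the centroid and `v_i` its displacement to the next
#' snapshot (scalar cross product in 2-D, vector norm in 3-D). Equals 1
#' for rigid rotation about the centroid and 0 for pure translation.
#' Computed on the stored (possibly strided) snapshots.
#'
#' @inheritParams straightness
#' @return A number in `[0, 1]`; 0 with attribute `stationary = TRUE` when
#'   nothing moves inside the window.
#' @export
helicity <- function(trajectory, window = NULL) {
  stopifnot(inherits(trajectory, "swarm_trajectory"))
  window <- check_window(trajectory, window)
  steps <- sort(unique(trajectory$states$step))
  steps <- steps[steps >= window[1] & steps <= window[2]]
  if (length(steps) < 2) stop("window must contain at least 2 stored states",
                              call. = FALSE)
  in_window <- dplyr::filter(trajectory$states,
                             .data$step >= window[1], .data$step <= window[2])
  mats <- lapply(split(in_window, in_window$step), position_matrix)
  mats <- mats[as.character(steps)]
  vals <- numeric(0)
  for (t in seq_len(length(mats) - 1)) {
    p0 <- mats[[t]]
    v <- mats[[t + 1]] - p0
    ctr <- colMeans(p0)
    r <- sweep(p0, 2, ctr)
    denom <- sum(sqrt(rowSums(r^2)) * sqrt(rowSums(v^2)))
    if (denom > 0) vals <- c(vals, cross_sum_norm(r, v) / denom)
  }
  if (length(vals) == 0) {
    return(structure(0, stationary = TRUE))
  }
  min(1, mean(vals))
}

# internal: first step of a sustained multi-component episode, from a
# (step, n_components) series; `window` is a step span
fission_step_from_series <- function(step, n_components, window) {
  split_now <- n_components > 1
  if (!any(split_now)) return(NA_integer_)
  r <- rle(split_now)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  res <- if (length(step) > 1) min(diff(step)) else 1L
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) {
      span <- step[ends[i]] - step[starts[i]] + res
      if (span >= window) return(as.integer(step[starts[i]]))
    }
  }
  NA_integer_
}

#' Detect group fission
#'
#' Fission is a sustained disconnection of the interaction digraph: the
#' weak-component count rises above one and stays there. The subgroups are
#' the weakly connected components of the final graph; because every
#' agent's K nearest neighbors lie inside its own weak component, each
#' subgroup necessarily has at least `K + 1` members.
#'
#' @param x Either a `swarm_trajectory` (uses the per-step component
#'   series recorded during the run) or a list of interaction graphs
#'   (ordered snapshots).
#' @param window Sustainment requirement. For a trajectory: a step span
#'   (default 500 steps). For a graph list: a number of consecutive
#'   snapshots (default 50).
#' @return A list with `fission_step` (first step of the sustained split,
#'   or `NA`), `n_subgroups`, and `subgroups` (list of agent-id vectors
#'   partitioning the group).
#' @export
detect_fission <- function(x, window = NULL) {
  if (inherits(x, "swarm_trajectory")) {
    if (is.null(window)) window <- 50 * x$stride
    fs <- fission_step_from_series(x$series$step, x$series$n_components,
                                   window)
    g <- interaction_graph(final_state(x), x$k)
  } else if (is.list(x) && length(x) > 0 && igraph::is_igraph(x[[1]])) {
    if (is.null(window)) window <- 50
    ncomp <- vapply(x, function(g) igraph::components(g, mode = "weak")$no,
                    numeric(1))
    steps <- vapply(seq_along(x), function(i) {
      s <- igraph::graph_attr(x[[i]], "step")
      if (is.null(s)) i else as.numeric(s)
    }, numeric(1))
    res <- if (length(steps) > 1) min(diff(steps)) else 1
    fs <- fission_step_from_series(steps, ncomp, window * res)
    g <- x[[length(x)]]
  } else {
    stop("x must be a swarm_trajectory or a non-empty list of igraphs",
         call. = FALSE)
  }
  comp <- igraph::components(g, mode = "weak")
  ids <- igraph::V(g)$agent_id
  subgroups <- unname(split(ids, comp$membership))
  list(fission_step = fs, n_subgroups = comp$no, subgroups = subgroups)
}

#' Classification thresholds for motion types
#'
#' The eight motion types are ordered by straightness (S) and helicity (H)
#' only; the type boundaries themselves are free choices and therefore
#' live in this configuration object rather than in the classifier logic.
#'
#' @param s_type1,s_type2,s_type3,s_type4 Descending straightness cut
#'   points separating types 1|2, 2|3, 3|4 and 4|rotational.
#' @param h_type6 Helicity at or above which a low-straightness orbit is
#'   type 6 rather than type 5.
#' @param h_orbit Helicity above which a stationary configuration with a
#'   static centroid counts as an orbiting state (torus) rather than a
#'   frozen aggregate (type 7).
#' @param settle_tol Relative fluctuation (range/mean over the analysis
#'   window) of the mean nearest-neighbor distance below which the group
#'   spacing counts as settled; unsettled non-stationary runs are the
#'   disordered type 8.
#' @param fission_window Step span a multi-component episode must last to
#'   count as fission (50 snapshots at the default stride of 10).
#' @param window_frac Fraction of the trajectory (from the end) used as
#'   the analysis window for S and H.
#' @return A named list of class `motion_thresholds`.
#' @export
motion_thresholds <- function(s_type1 = 0.9, s_type2 = 0.7, s_type3 = 0.45,
                              s_type4 = 0.2, h_type6 = 0.95, h_orbit = 0.5,
                              settle_tol = 0.05,
                              fission_window = 500, window_frac = 0.25) {
  stopifnot(s_type1 > s_type2, s_type2 > s_type3, s_type3 > s_type4,
            s_type4 > 0, h_type6 > 0, h_type6 <= 1, h_orbit > 0,
            h_orbit <= 1)
  structure(list(s_type1 = s_type1, s_type2 = s_type2, s_type3 = s_type3,
                 s_type4 = s_type4, h_type6 = h_type6, h_orbit = h_orbit,
                 settle_tol = settle_tol, fission_window = fission_window,
                 window_frac = window_frac),
            class = "motion_thresholds")
}

#' Classify the emergent collective motion
#'
#' Decision cascade over a finished trajectory:
#' 1. a **sustained split** of the interaction digraph (weak-component
#'    count above one for at least `fission_window` steps, still
#'    disconnected at the end) is **fission** when the fragments keep
#'    moving as coherent subgroups, but **type 8** (unformed motion) when
#'    the whole configuration has frozen into static scattered remnants —
#'    small fragments whose internal graphs are complete are symmetric and
#'    generate no net drive, so low-K fragmentation ends as motionless
#'    debris rather than traveling subgroups;
#' 2. a connected group that freezes — stationarity sustained, centroid
#'    stopped, no orbital angular momentum (`H < h_orbit`) — is the rapid
#'    aggregation **type 7**;
#' 3. **type 8** also covers runs that neither become stationary nor
#'    settle their mean nearest-neighbor spacing;
#' 4. everything else maps to types 1-6 from the straightness/helicity
#'    pair: S descending from near 1 (straight translation, type 1)
#'    through the helical mixtures (types 3-4) to closed orbits
#'    (types 5-6, split by H).
#'
#' @param trajectory A [run_swarm()] result.
#' @param thresholds A [motion_thresholds()] configuration.
#' @return A `behavior_report`: list with `motion_type` (one of
#'   `"1"`..`"8"` or `"fission"`), `straightness`, `helicity`, `window`,
#'   `subgroups`, `n_subgroups`, `fission_step`, `stationary_at`, `n`,
#'   `k`.
#' @examples
#' pos <- scenario_uniform_cloud(15, seed = 1)
#' traj <- run_swarm(pos, k = 14, params = swarm_params(t_max = 5000))
#' classify_motion(traj)
#' @export
classify_motion <- function(trajectory, thresholds = motion_thresholds()) {
  stopifnot(inherits(trajectory, "swarm_trajectory"),
            inherits(thresholds, "motion_thresholds"))
  params <- trajectory$params
  window <- default_window(trajectory, thresholds$window_frac)
  s <- as.numeric(straightness(trajectory, window))
  h <- as.numeric(helicity(trajectory, window))
  fis <- detect_fission(trajectory, window = thresholds$fission_window)
  final_split <- tail(trajectory$series$n_components, 1) > 1

  # frozen: relative configuration stationary and the group as a whole at rest
  at_rest <- !is.na(trajectory$stationary_at) &&
    final_centroid_speed(trajectory) < params$stability_tol * params$d_e

  type <- NULL
  if (!is.na(fis$fission_step) && final_split) {
    type <- if (at_rest) "8" else "fission"
  } else if (at_rest && h < thresholds$h_orbit) {
    type <- "7"
  } else if (is.na(trajectory$stationary_at) &&
             !nn_settled(trajectory, window, thresholds$settle_tol)) {
    type <- "8"
  } else if (s >= thresholds$s_type1) {
    type <- "1"
  } else if (s >= thresholds$s_type2) {
    type <- "2"
  } else if (s >= thresholds$s_type3) {
    type <- "3"
  } else if (s >= thresholds$s_type4) {
    type <- "4"
  } else {
    type <- if (h >= thresholds$h_type6) "6" else "5"
  }

  structure(
    list(motion_type = type, straightness = s, helicity = h,
         window = window, subgroups = fis$subgroups,
         n_subgroups = fis$n_subgroups,
         fission_step = if (type == "fission") fis$fission_step
                        else NA_integer_,
         stationary_at = trajectory$stationary_at,
         n = trajectory$n, k = trajectory$k),
    class = "behavior_report"
  )
}

# has the mean nearest-neighbor distance settled inside the window?
nn_settled <- function(trajectory, window, settle_tol) {
  sr <- dplyr::filter(trajectory$series,
                      .data$step >= window[1], .data$step <= window[2])
  v <- sr$mean_nn_dist
  v <- v[is.finite(v)]
  if (length(v) < 2) return(TRUE)
  m <- mean(v)
  if (m == 0) return(TRUE)
  (max(v) - min(v)) / m <= settle_tol
}

#' @export
print.behavior_report <- function(x, ...) {
  cat(sprintf("<behavior_report> N=%d K=%d  type %s\n", x$n, x$k,
              x$motion_type))
  cat(sprintf("  straightness=%.3f helicity=%.3f  window [%d, %d]\n",
              x$straightness, x$helicity, x$window[1], x$window[2]))
  if (x$motion_type == "fission") {
    cat(sprintf("  fission at step %d into %d subgroups (sizes %s)\n",
                x$fission_step, x$n_subgroups,
                paste(lengths(x$subgroups), collapse = ", ")))
  }
  invisible(x)
}

#' Tidy a behavior report
#'
#' @param x A `behavior_report`.
#' @param ... Unused.
#' @return A one-row tibble: `motion_type`, `straightness`, `helicity`,
#'   `n_subgroups`, `fission_step`, `stationary_at`, `n`, `k`.
#' @export
tidy.behavior_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, motion_type = x$motion_type,
    straightness = x$straightness, helicity = x$helicity,
    n_subgroups = x$n_subgroups, fission_step = x$fission_step,
    stationary_at = x$stationary_at
  )
}

#' @rdname tidy.behavior_report
#' @export
glance.behavior_report <- function(x, ...) tidy(x)
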