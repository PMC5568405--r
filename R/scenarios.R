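# uniform points in a cube sized so the expected nearest-neighbor spacing
# matches `spacing` (Poisson-process approximation: E[nn] ~= 0.554 rho^-1/3
# in 3-D, 0.5 rho^-1/2 in 2-D); coincidences removed by rejection
cloud_matrix <- function(n, dims, spacing, min_sep = 1e-3) {
  side <- if (dims == 3) {
    spacing / 0.5539 * n^(1 / 3)
  } else {
    2 * spacing * sqrt(n)
  }
  if (n == 1) return(matrix(rep(side / 2, dims), 1, dims))
  m <- matrix(stats::runif(n * dims, 0, side), n, dims)
  for (tries in 1:1000) {
    d <- as.matrix(dist(m))
    diag(d) <- Inf
    bad <- unique(which(apply(d, 1, min) <= min_sep))
    if (length(bad) == 0) return(m)
    m[bad, ] <- matrix(stats::runif(length(bad) * dims, 0, side),
                       length(bad), dims)
  }
  stop("could not generate a cloud without near-coincident agents",
       call. = FALSE)
}

# random unit vector
unit_vector <- function(dims) {
  v <- stats::rnorm(dims)
  v / sqrt(sum(v^2))
}

#' Well-distributed cloud of agents
#'
#' Draws `n` agents uniformly in a cube scaled so the expected
#' nearest-neighbor spacing is about `spacing`. The default spacing of 8.6
#' length units sits between the equilibrium distance (5.2) and the
#' saturation threshold, i.e. in the loosely distributed regime where
#' attraction dominates at the start of a run.
#'
#' @param n Number of agents (>= 1).
#' @param dims Spatial dimensionality (2 or 3).
#' @param spacing Target mean nearest-neighbor distance (length units).
#' @param seed RNG seed; generation is a pure function of the arguments
#'   and leaves the caller's RNG state untouched.
#' @return A positions tibble (`agent_id`, `x`, `y`\[, `z`\]) with
#'   attribute `step = 0`.
#' @examples
#' scenario_uniform_cloud(16, seed = 1)
#' @export
scenario_uniform_cloud <- function(n, dims = 3, spacing = 8.6, seed = 1L) {
  n <- check_count(n, "n")
  stopifnot(dims %in% c(2, 3), spacing > 0)
  m <- with_local_seed(seed, cloud_matrix(n, dims, spacing))
  positions_tibble(m, step = 0L)
}

#' Cloud with one isolated individual
#'
#' `n - 1` agents form a well-distributed cloud; the last agent is placed
#' `isolation_offset` away from the cloud centroid along a random
#' direction. The offset must exceed the saturation threshold
#' `(d_e + d_h)/2` so the isolated agent initially feels only the
#' saturated attraction.
#'
#' @inheritParams scenario_uniform_cloud
#' @param isolation_offset Distance of the isolated agent from the cloud
#'   centroid; must exceed `(d_e + d_h)/2`.
#' @param params A [swarm_params()] used only to validate the offset.
#' @return A positions tibble; the isolated agent is the highest
#'   `agent_id`.
#' @export
scenario_isolated_individual <- function(n, dims = 3, spacing = 8.6,
                                         isolation_offset = 20, seed = 1L,
                                         params = swarm_params()) {
  n <- check_count(n, "n", min = 2)
  stopifnot(dims %in% c(2, 3), spacing > 0)
  if (isolation_offset <= saturation_threshold(params)) {
    stop("isolation_offset must exceed the saturation threshold (d_e + d_h)/2",
         call. = FALSE)
  }
  m <- with_local_seed(seed, {
    cloud <- cloud_matrix(n - 1, dims, spacing)
    ctr <- colMeans(cloud)
    rbind(cloud, ctr + isolation_offset * unit_vector(dims))
  })
  positions_tibble(m, step = 0L)
}

#' Pre-formed subgroups
#'
#' Places `n_subgroups` compact clouds whose centroids are `separation`
#' apart (pairwise for 2 subgroups, adjacent on a regular polygon for
#' more), each with within-cloud spacing near the equilibrium distance —
#' emulating groups in which collective behavior has already emerged
#' before the run starts.
#'
#' @inheritParams scenario_uniform_cloud
#' @param n_subgroups Number of pre-formed subgroups (>= 2).
#' @param spacing Within-subgroup nearest-neighbor spacing; defaults to
#'   the equilibrium distance 5.2.
#' @param separation Distance between (adjacent) subgroup centroids; must
#'   exceed `d_h`.
#' @param params A [swarm_params()] used only to validate `separation`.
#' @return A positions tibble; agents are assigned to subgroups in
#'   contiguous `agent_id` blocks, as evenly as possible.
#' @export
scenario_preformed_subgroups <- function(n, n_subgroups = 2, dims = 3,
                                         spacing = 5.2, separation = 52,
                                         seed = 1L, params = swarm_params()) {
  n <- check_count(n, "n", min = 2)
  n_subgroups <- check_count(n_subgroups, "n_subgroups", min = 2)
  stopifnot(dims %in% c(2, 3), spacing > 0, n_subgroups <= n)
  if (separation <= params$d_h) {
    stop("separation must exceed d_h", call. = FALSE)
  }
  sizes <- diff(floor(seq(0, n, length.out = n_subgroups + 1)))
  centers <- if (n_subgroups == 2) {
    rbind(c(-separation / 2, rep(0, dims - 1)),
          c(separation / 2, rep(0, dims - 1)))
  } else {
    # regular polygon in the x-y plane, adjacent centroids `separation` apart
    rad <- separation / (2 * sin(pi / n_subgroups))
    ang <- 2 * pi * (seq_len(n_subgroups) - 1) / n_subgroups
    cbind(rad * cos(ang), rad * sin(ang),
          matrix(0, n_subgroups, dims - 2))[, seq_len(dims), drop = FALSE]
  }
  m <- with_local_seed(seed, {
    do.call(rbind, lapply(seq_len(n_subgroups), function(g) {
      cl <- cloud_matrix(sizes[g], dims, spacing)
      sweep(cl, 2, colMeans(cl)) + matrix(centers[g, ], sizes[g], dims,
                                          byrow = TRUE)
    }))
  })
  positions_tibble(m, step = 0L)
}

#' Generate an initial configuration by scenario name
#'
#' Dispatcher over the three initial-condition families:
#' `"uniform_cloud"`, `"isolated_individual"`, `"preformed_subgroups"`.
#'
#' @param kind Scenario name.
#' @param n Number of agents.
#' @param ... Passed to the scenario generator.
#' @return A positions tibble.
#' @export
generate_scenario <- function(kind = c("uniform_cloud",
                                       "isolated_individual",
                                       "preformed_subgroups"),
                              n, ...) {
  kind <- match.arg(kind)
  switch(kind,
         uniform_cloud = scenario_uniform_cloud(n, ...),
         isolated_individual = scenario_isolated_individual(n, ...),
         preformed_subgroups = scenario_preformed_subgroups(n, ...))
}
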