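#' Pairwise interaction force magnitude
#'
#' Evaluates the piecewise pair force at one or more inter-agent distances.
#' The force is repulsive for `d_l < x < d_e` with magnitude
#' `k1 * (1/x - 1/d_e)`, attractive with magnitude
#' `k2 * sin((x - d_e) * pi / (d_h - d_e))` for
#' `d_e < x <= (d_e + d_h)/2`, saturates at `k3` beyond the threshold
#' `(d_e + d_h)/2`, and is zero otherwise (including exactly at `d_e` and at
#' or below `d_l`). The magnitude is nonnegative on every branch; the sense
#' (toward or away from the neighbor) is carried by the branch label.
#'
#' @param x Numeric vector of pairwise distances (finite, >= 0).
#' @param params A [swarm_params()] object.
#' @return A tibble with columns `x`, `force` (nonnegative magnitude) and
#'   `branch` (one of `"repulsive"`, `"attractive_sin"`,
#'   `"attractive_saturated"`, `"none"`).
#' @examples
#' pair_force(c(2.6, 5.2, 8.6, 20))
#' @export
pair_force <- function(x, params = swarm_params()) {
  stopifnot(inherits(params, "swarm_params"))
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    stop("x must be finite numeric", call. = FALSE)
  }
  if (any(x < 0)) stop("x must be nonnegative", call. = FALSE)
  mid <- saturation_threshold(params)
  branch <- rep("none", length(x))
  force <- numeric(length(x))

  rep_i <- x > params$d_l & x < params$d_e
  sin_i <- x > params$d_e & x <= mid
  sat_i <- x > mid

  force[rep_i] <- params$k1 * (1 / x[rep_i] - 1 / params$d_e)
  force[sin_i] <- params$k2 *
    sin((x[sin_i] - params$d_e) * pi / (params$d_h - params$d_e))
  force[sat_i] <- params$k3
  branch[rep_i] <- "repulsive"
  branch[sin_i] <- "attractive_sin"
  branch[sat_i] <- "attractive_saturated"

  tibble::tibble(x = x, force = force, branch = branch)
}

# attraction / repulsion magnitudes for a distance vector (internal,
# vectorised; mirrors the compiled kernel)
force_components <- function(x, params) {
  mid <- saturation_threshold(params)
  attract <- ifelse(
    x > params$d_e & x <= mid,
    params$k2 * sin((x - params$d_e) * pi / (params$d_h - params$d_e)),
    ifelse(x > mid, params$k3, 0)
  )
  repulse <- ifelse(x > params$d_l & x < params$d_e,
                    params$k1 * (1 / x - 1 / params$d_e), 0)
  list(attract = attract, repulse = repulse)
}

#' Resultant force on every agent
#'
#' Sums the weighted pair forces `a * attraction - b * repulsion` over each
#' agent's K nearest neighbors, resolved along the unit vector from the
#' agent toward each neighbor, componentwise on every coordinate axis.
#'
#' @param positions Tibble of agent coordinates with columns
#'   `agent_id`, `x`, `y`\[, `z`\].
#' @param k Number of nearest neighbors each agent perceives
#'   (`0 <= k <= N - 1`).
#' @param params A [swarm_params()] object.
#' @return A tibble with `agent_id` and force components `f_x`, `f_y`\[,
#'   `f_z`\].
#' @examples
#' pos <- tibble::tibble(agent_id = 0:1, x = c(0, 20), y = 0, z = 0)
#' interaction_forces(pos, k = 1)
#' @export
interaction_forces <- function(positions, k, params = swarm_params()) {
  m <- position_matrix(positions)
  n <- nrow(m)
  k <- check_count(k, "k", min = 0)
  if (k > n - 1) stop("k must be at most N - 1", call. = FALSE)
  f <- matrix(0, n, ncol(m))
  if (k > 0 && n > 1) {
    d <- as.matrix(dist(m))
    for (i in seq_len(n)) {
      nb <- knn_indices(d[i, ], i, k)
      xd <- d[i, nb]
      if (any(xd == 0)) {
        stop("degenerate geometry: coincident agents among neighbors",
             call. = FALSE)
      }
      fc <- force_components(xd, params)
      scale <- (params$a * fc$attract - params$b * fc$repulse) / xd
      for (jj in seq_along(nb)) {
        f[i, ] <- f[i, ] + scale[jj] * (m[nb[jj], ] - m[i, ])
      }
    }
  }
  out <- tibble::as_tibble(setNames(as.data.frame(f),
                                    paste0("f_", coord_names(ncol(m)))))
  dplyr::bind_cols(tibble::tibble(agent_id = as.integer(rownames(m))), out)
}

#' Advance the swarm by one step
#'
#' Recomputes the K-nearest-neighbor sets from the current positions,
#' evaluates the resultant forces, and applies the first-order position
#' update `S(t+1) = S(t) + c * F(t)` synchronously for all agents.
#' Deterministic given the state.
#'
#' @inheritParams interaction_forces
#' @return A positions tibble of the same shape with the `step` attribute
#'   (if present) incremented by 1.
#' @examples
#' pos <- tibble::tibble(agent_id = 0:1, x = c(0, 20), y = 0, z = 0)
#' swarm_step(pos, k = 1)
#' @export
swarm_step <- function(positions, k, params = swarm_params()) {
  m <- position_matrix(positions)
  f <- interaction_forces(positions, k, params)
  fm <- as.matrix(f[, -1, drop = FALSE])
  step <- attr(positions, "step")
  positions_tibble(m + params$c * fm,
                   agent_id = as.integer(rownames(m)),
                   step = if (is.null(step)) NULL else step + 1L)
}
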