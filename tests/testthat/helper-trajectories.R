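# Build a swarm_trajectory object from prescribed kinematics, for testing
# the order parameters and the classifier on motions whose S and H are
# known in closed form. `pos_fun(t)` returns an n x dims coordinate matrix.
synthetic_trajectory <- function(pos_fun, n_steps, dims = 2, k = 1,
                                 params = NULL) {
  if (is.null(params)) {
    params <- swarm_params(dims = dims, t_max = max(n_steps, 1))
  }
  steps <- 0:n_steps
  mats <- lapply(steps, pos_fun)
  n <- nrow(mats[[1]])
  states <- dplyr::bind_rows(lapply(seq_along(steps), function(i) {
    dplyr::bind_cols(
      tibble::tibble(step = steps[i], agent_id = seq_len(n) - 1L),
      tibble::as_tibble(stats::setNames(as.data.frame(mats[[i]]),
                                        c("x", "y", "z")[seq_len(dims)]))
    )
  }))
  centroid <- dplyr::bind_rows(lapply(seq_along(steps), function(i) {
    ctr <- colMeans(mats[[i]])
    dplyr::bind_cols(tibble::tibble(step = steps[i]),
                     tibble::as_tibble(as.list(stats::setNames(
                       ctr, c("x", "y", "z")[seq_len(dims)]))))
  }))
  series <- tibble::tibble(
    step = steps,
    n_components = 1L,
    mean_nn_dist = vapply(mats, function(m) {
      if (nrow(m) < 2) return(NA_real_)
      d <- as.matrix(dist(m)); diag(d) <- Inf
      mean(apply(d, 1, min))
    }, numeric(1)),
    max_dist_change = NA_real_
  )
  structure(
    list(states = states, centroid = centroid, series = series,
         params = params, k = k, n = n, dims = dims, stride = 1L,
         n_steps = as.integer(n_steps), stationary_at = NA_integer_),
    class = "swarm_trajectory"
  )
}

# positions tibble from a coordinate matrix, 0-based ids
positions_df <- function(m) {
  out <- tibble::as_tibble(stats::setNames(as.data.frame(m),
                                           c("x", "y", "z")[seq_len(ncol(m))]))
  dplyr::bind_cols(tibble::tibble(agent_id = seq_len(nrow(m)) - 1L), out)
}

# ring of n agents, radius r, rotated by angle theta
ring_at <- function(n, r, theta) {
  ang <- 2 * pi * (seq_len(n) - 1) / n + theta
  cbind(r * cos(ang), r * sin(ang))
}
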