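#' Write agent positions to CSV
#'
#' Headered CSV with columns `agent_id`, `x`, `y`\[, `z`\]; 0-based agent
#' ids, coordinates in the same length units as the model distances.
#'
#' @param positions Positions tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_positions <- function(positions, path) {
  m <- position_matrix(positions)
  readr::write_csv(positions_tibble(m, agent_id = as.integer(rownames(m))),
                   path)
  invisible(path)
}

#' Read agent positions from CSV
#'
#' @param path CSV file with columns `agent_id`, `x`, `y`\[, `z`\].
#' @param dims Optional expected dimensionality; a mismatch is an error.
#' @return A positions tibble with attribute `step = 0`.
#' @export
read_positions <- function(path, dims = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  cols <- intersect(c("x", "y", "z"), names(df))
  if (!"agent_id" %in% names(df) || length(cols) < 2 ||
      !identical(cols, c("x", "y", "z")[seq_along(cols)])) {
    stop("file must have columns agent_id, x, y[, z]: ", path, call. = FALSE)
  }
  file_dims <- length(cols)
  if (!is.null(dims) && file_dims != dims) {
    stop(sprintf("file is %d-dimensional but %d dimensions were requested: %s",
                 file_dims, dims, path), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[, c("agent_id", cols)]) |
                 !apply(as.matrix(df[, cols]), 1, function(r) all(is.finite(r))))
  if (length(bad) > 0) {
    stop("malformed coordinate row(s) at line(s) ",
         paste(bad + 1, collapse = ", "), " of ", path, call. = FALSE)
  }
  if (anyDuplicated(df$agent_id)) {
    dup <- which(duplicated(df$agent_id))[1]
    stop("duplicate agent_id at line ", dup + 1, " of ", path, call. = FALSE)
  }
  out <- tibble::as_tibble(df[, c("agent_id", cols)])
  out$agent_id <- as.integer(out$agent_id)
  attr(out, "step") <- 0L
  out
}

#' Write a trajectory's stored states to CSV
#'
#' Long format with columns `step`, `agent_id`, `x`, `y`\[, `z`\].
#'
#' @param trajectory A [run_swarm()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "swarm_trajectory"))
  readr::write_csv(trajectory$states, path)
  invisible(path)
}

#' Rebuild a trajectory from a stored state CSV
#'
#' Reconstructs a `swarm_trajectory` from a long CSV written by
#' [write_trajectory()]. The centroid path and the component/spacing
#' series are recomputed at the stored (possibly strided) resolution;
#' `stationary_at` is unknown for a loaded trajectory and set to `NA`.
#'
#' @param path CSV with columns `step`, `agent_id`, `x`, `y`\[, `z`\].
#' @param k Number of perceived neighbors used to rebuild the interaction
#'   graphs.
#' @param params A [swarm_params()]; `dims` must match the file.
#' @return A `swarm_trajectory`.
#' @export
read_trajectory <- function(path, k, params = swarm_params()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  cols <- intersect(c("x", "y", "z"), names(df))
  if (!all(c("step", "agent_id") %in% names(df)) || length(cols) < 2) {
    stop("file must have columns step, agent_id, x, y[, z]: ", path,
         call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$step, .data$agent_id)
  steps <- unique(df$step)
  n <- sum(df$step == steps[1])
  k <- check_count(k, "k", min = 0)

  per_step <- lapply(steps, function(s) {
    position_matrix(dplyr::filter(df, .data$step == s))
  })
  centroid <- purrr::map_dfr(seq_along(steps), function(i) {
    ctr <- colMeans(per_step[[i]])
    dplyr::bind_cols(tibble::tibble(step = as.integer(steps[i])),
                     tibble::as_tibble(as.list(setNames(ctr,
                                                        coord_names(length(ctr))))))
  })
  series <- purrr::map_dfr(seq_along(steps), function(i) {
    m <- per_step[[i]]
    d <- as.matrix(dist(m))
    diag(d) <- Inf
    g <- interaction_graph(positions_tibble(m), min(k, n - 1))
    tibble::tibble(step = as.integer(steps[i]),
                   n_components = igraph::components(g, mode = "weak")$no,
                   mean_nn_dist = if (n > 1) mean(apply(d, 1, min)) else NA_real_,
                   max_dist_change = NA_real_)
  })
  stride <- if (length(steps) > 1) as.integer(min(diff(steps))) else 1L

  structure(
    list(states = tibble::as_tibble(df[, c("step", "agent_id", cols)]),
         centroid = centroid, series = series, params = params,
         k = k, n = n, dims = length(cols), stride = stride,
         n_steps = as.integer(max(steps)), stationary_at = NA_integer_),
    class = "swarm_trajectory"
  )
}

#' Serialize a behavior report as JSON
#'
#' @param report A [classify_motion()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_behavior_json <- function(report, path) {
  stopifnot(inherits(report, "behavior_report"))
  jsonlite::write_json(
    list(motion_type = report$motion_type,
         straightness = report$straightness,
         helicity = report$helicity,
         n_subgroups = report$n_subgroups,
         fission_step = report$fission_step,
         subgroups = report$subgroups),
    path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}
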