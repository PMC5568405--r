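# internal helpers shared across modules

coord_names <- function(dims) c("x", "y", "z")[seq_len(dims)]

# Extract the coordinate matrix (agents x dims) from a positions tibble,
# ordered by agent_id. Accepts columns agent_id, x, y[, z].
position_matrix <- function(positions) {
  stopifnot(is.data.frame(positions))
  cols <- intersect(c("x", "y", "z"), names(positions))
  if (length(cols) < 2) {
    stop("positions must have coordinate columns x, y[, z]", call. = FALSE)
  }
  if (!"agent_id" %in% names(positions)) {
    positions$agent_id <- seq_len(nrow(positions)) - 1L
  }
  ord <- order(positions$agent_id)
  m <- as.matrix(positions[ord, cols, drop = FALSE])
  if (!all(is.finite(m))) stop("all coordinates must be finite", call. = FALSE)
  rownames(m) <- positions$agent_id[ord]
  m
}

positions_tibble <- function(m, agent_id = NULL, step = NULL) {
  dims <- ncol(m)
  if (is.null(agent_id)) agent_id <- seq_len(nrow(m)) - 1L
  out <- tibble::as_tibble(setNames(as.data.frame(m), coord_names(dims)))
  out <- dplyr::bind_cols(tibble::tibble(agent_id = as.integer(agent_id)), out)
  if (!is.null(step)) attr(out, "step") <- as.integer(step)
  out
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
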