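# indices of the k nearest to agent i given one row of the distance matrix;
# ties broken by ascending index, result ordered by (distance, index)
knn_indices <- function(drow, i, k) {
  cand <- setdiff(seq_along(drow), i)
  cand[order(drow[cand], cand)][seq_len(k)]
}

#' K nearest neighbors of each agent
#'
#' Ranks the other agents by Euclidean distance and keeps the `k` nearest,
#' regardless of how far away they are (topological, not metric,
#' perception). Ties are broken by ascending agent id, and each list is
#' ordered by (distance, id).
#'
#' @inheritParams interaction_forces
#' @param agents Optional vector of agent ids to restrict to (default: all).
#' @return A tibble with one row per (agent, neighbor) pair: `agent_id`,
#'   `rank` (1 = nearest), `neighbor_id`, `distance`.
#' @examples
#' pos <- tibble::tibble(agent_id = 0:3, x = 0:3, y = 0)
#' k_nearest_neighbors(pos, k = 2)
#' @export
k_nearest_neighbors <- function(positions, k, agents = NULL) {
  m <- position_matrix(positions)
  n <- nrow(m)
  k <- check_count(k, "k", min = 0)
  if (k > n - 1) {
    stop("k must be at most N - 1 (got k = ", k, ", N = ", n, ")",
         call. = FALSE)
  }
  ids <- as.integer(rownames(m))
  if (is.null(agents)) agents <- ids
  if (k == 0 || n == 1) {
    return(tibble::tibble(agent_id = integer(), rank = integer(),
                          neighbor_id = integer(), distance = double()))
  }
  d <- as.matrix(dist(m))
  rows <- lapply(match(agents, ids), function(i) {
    nb <- knn_indices(d[i, ], i, k)
    tibble::tibble(agent_id = ids[i], rank = seq_len(k),
                   neighbor_id = ids[nb], distance = unname(d[i, nb]))
  })
  dplyr::bind_rows(rows)
}

#' Directed interaction graph at one step
#'
#' Builds the who-perceives-whom digraph from a set of positions: an edge
#' runs from the perceived neighbor `j` to the perceiver `i` whenever `j`
#' is among `i`'s `k` nearest agents (information flows toward the
#' perceiver). Every in-degree therefore equals `k` and the edge count is
#' `N * k`.
#'
#' @inheritParams interaction_forces
#' @param step Optional time index recorded as a graph attribute.
#' @return An [igraph][igraph::igraph-package] directed graph with vertex
#'   attribute `agent_id` (0-based) and graph attributes `n`, `k`, `step`.
#' @examples
#' pos <- tibble::tibble(agent_id = 0:4, x = c(0, 1, 2, 5, 9), y = 0)
#' g <- interaction_graph(pos, k = 2)
#' igraph::degree(g, mode = "in")
#' @export
interaction_graph <- function(positions, k, step = NULL) {
  nb <- k_nearest_neighbors(positions, k)
  m <- position_matrix(positions)
  ids <- as.integer(rownames(m))
  g <- igraph::make_empty_graph(n = nrow(m), directed = TRUE)
  igraph::V(g)$agent_id <- ids
  igraph::V(g)$name <- as.character(ids)
  if (nrow(nb) > 0) {
    # edge j -> i: j is perceived by i
    g <- igraph::add_edges(g, rbind(match(nb$neighbor_id, ids),
                                    match(nb$agent_id, ids)))
  }
  g <- igraph::set_graph_attr(g, "n", nrow(m))
  g <- igraph::set_graph_attr(g, "k", as.integer(k))
  if (!is.null(step)) g <- igraph::set_graph_attr(g, "step", as.integer(step))
  g
}

#' Out-degree distribution of an interaction graph
#'
#' The out-degree of an agent counts how many others perceive it — its
#' influence. In a stationary group out-degrees concentrate near `k`, with
#' a single high-out-degree agent (the leader effect).
#'
#' @param graph A directed [igraph][igraph::igraph-package] graph, e.g. from
#'   [interaction_graph()].
#' @return A tibble with columns `out_degree` and `n_agents`; counts sum to
#'   the number of vertices.
#' @export
out_degree_distribution <- function(graph) {
  deg <- igraph::degree(graph, mode = "out")
  tab <- table(factor(deg, levels = sort(unique(deg))))
  tibble::tibble(out_degree = as.integer(names(tab)),
                 n_agents = as.integer(tab))
}

#' Write a graph snapshot to disk
#'
#' @param graph A directed igraph, typically from [interaction_graph()].
#' @param path Output file.
#' @param format `"edgelist"` for whitespace-delimited `source target`
#'   pairs (0-based agent ids), or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_snapshot <- function(graph, path,
                                 format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph, names = FALSE)
    ids <- igraph::V(graph)$agent_id
    writeLines(paste(ids[el[, 1]], ids[el[, 2]]), path)
  }
  invisible(path)
}
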