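test_that("density equals K/(N-1) for nearest-neighbor graphs", {
  m <- matrix(stats::runif(21 * 3), 21, 3)
  expect_equal(graph_density(interaction_graph(positions_df(m), 20)), 1)
  m16 <- matrix(stats::runif(16 * 3), 16, 3)
  expect_equal(graph_density(interaction_graph(positions_df(m16), 7)), 7 / 15)
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:50, 1)
    k <- sample(1:(n - 1), 1)
    g <- interaction_graph(positions_df(matrix(stats::runif(n * 3), n, 3)), k)
    expect_equal(graph_density(g), k / (n - 1))
  }
  g1 <- igraph::make_empty_graph(1)
  expect_error(graph_density(g1), "fewer than 2")
})

test_that("density is constant along a whole trajectory", {
  traj <- run_swarm(scenario_uniform_cloud(23, seed = 1), 6,
                    params = swarm_params(t_max = 500))
  met <- metrics_timeseries(traj)
  expect_true(all(met$density == 6 / 22))
})

test_that("network entropy matches hand-computed histograms", {
  # all out-degrees equal -> zero
  m <- matrix(stats::runif(10 * 3), 10, 3)
  expect_equal(network_entropy(interaction_graph(positions_df(m), 9)), 0)
  # out-degrees {2, 2, 4}: -(2/3)ln(2/3) - (1/3)ln(1/3)
  g <- igraph::make_empty_graph(3, directed = TRUE)
  g <- igraph::add_edges(g, c(1,2, 1,3,  2,1, 2,3,  3,1, 3,1, 3,2, 3,2))
  expect_equal(sort(unname(igraph::degree(g, mode = "out"))), c(2, 2, 4))
  expect_equal(network_entropy(g), 0.63651, tolerance = 1e-5)
  expect_equal(network_entropy(g),
               oracle_entropy(igraph::degree(g, mode = "out")))
})

test_that("entropy is zero iff the out-degree distribution is single-valued", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    k <- sample(1:(n - 1), 1)
    g <- interaction_graph(positions_df(matrix(stats::runif(n * 2), n, 2)),
                           k)
    deg <- igraph::degree(g, mode = "out")
    if (length(unique(deg)) == 1) {
      expect_equal(network_entropy(g), 0)
    } else {
      expect_gt(network_entropy(g), 0)
    }
  }
})

test_that("geodesic distances average over reachable ordered pairs", {
  # complete digraph
  full <- interaction_graph(positions_df(matrix(stats::runif(6 * 2), 6, 2)),
                            5)
  geo <- network_geodesic(full)
  expect_equal(geo$avg_geodesic, 1)
  expect_equal(geo$reachable_pair_fraction, 1)
  # directed 3-cycle: paths 1,2,1,2,1,2
  cyc <- igraph::make_empty_graph(3, directed = TRUE)
  cyc <- igraph::add_edges(cyc, c(1,2, 2,3, 3,1))
  expect_equal(network_geodesic(cyc)$avg_geodesic, 1.5)
  # two isolated dyads: cross pairs unreachable and excluded
  dy <- igraph::make_empty_graph(4, directed = TRUE)
  dy <- igraph::add_edges(dy, c(1,2, 2,1, 3,4, 4,3))
  geo <- network_geodesic(dy)
  expect_equal(geo$avg_geodesic, 1)
  expect_equal(geo$reachable_pair_fraction, 4 / 12)
  none <- igraph::make_empty_graph(3, directed = TRUE)
  expect_error(network_geodesic(none), "reachable")
})

test_that("clustering coefficient handles canonical graphs", {
  full <- interaction_graph(positions_df(matrix(stats::runif(7 * 2), 7, 2)),
                            6)
  expect_equal(network_clustering(full), 1)
  star <- igraph::make_empty_graph(6, directed = TRUE)
  star <- igraph::add_edges(star, rbind(2:6, rep(1, 5)))
  expect_equal(network_clustering(star), 0)
})

test_that("metrics agree with brute-force matrix oracles", {
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(4:20, 1)
    k <- sample(1:(n - 1), 1)
    m <- matrix(stats::runif(n * 3, 0, 20), n, 3)
    g <- interaction_graph(positions_df(m), k)
    A <- oracle_knn_adjacency(m, k)
    D <- oracle_geodesics(A)
    off <- D[row(D) != col(D)]
    geo <- network_geodesic(g)
    expect_equal(geo$avg_geodesic, mean(off[is.finite(off)]))
    expect_equal(geo$reachable_pair_fraction, mean(is.finite(off)))
    expect_equal(network_clustering(g), oracle_clustering(A))
    expect_equal(network_entropy(g), oracle_entropy(colSums(t(A))))
    expect_equal(graph_density(g), sum(A) / (n * (n - 1)))
  }
})

test_that("adding edges never lengthens paths between already-reachable pairs", {
  set.seed(29)
  m <- matrix(stats::runif(15 * 2, 0, 10), 15, 2)
  ks <- c(2, 5, 9, 14)
  dists <- lapply(ks, function(k) {
    igraph::distances(interaction_graph(positions_df(m), k), mode = "out")
  })
  for (i in seq_len(length(ks) - 1)) {
    lo <- dists[[i]]
    hi <- dists[[i + 1]]
    reach <- is.finite(lo) & row(lo) != col(lo)
    expect_true(all(hi[reach] <= lo[reach]))
    expect_lte(mean(hi[reach]), mean(lo[reach]))
  }
})

test_that("a single-state trajectory yields one metrics row", {
  pos <- scenario_uniform_cloud(6, seed = 9)
  traj <- run_swarm(pos, 5, params = swarm_params(t_max = 1,
                                                  stability_window = 1))
  met <- metrics_timeseries(traj)
  expect_gte(nrow(met), 1)
  expect_true(all(c("density", "entropy", "avg_geodesic", "avg_clustering",
                    "reachable_pair_fraction", "n_components") %in%
                    names(met)))
})

test_that("the geodesic distance drops exactly at the fission critical point", {
  tr <- NULL
  for (seed in 1:4) {
    cand <- run_swarm(scenario_uniform_cloud(23, seed = seed), 6, stride = 1)
    fis <- detect_fission(cand)
    if (!is.na(fis$fission_step) &&
        tail(cand$series$n_components, 1) > 1) {
      tr <- cand
      fs <- fis$fission_step
      break
    }
  }
  expect_false(is.null(tr))
  win <- max(0, fs - 60):min(tr$n_steps, fs + 60)
  met <- purrr::map_dfr(win, function(s) {
    pos <- dplyr::filter(tr$states, step == s)
    network_metrics(interaction_graph(pos, 6, step = s))
  })
  # single least-squares change-point of each series
  changepoint <- function(x) {
    n <- length(x)
    cost <- vapply(2:(n - 1), function(i) {
      a <- x[1:i]
      b <- x[(i + 1):n]
      sum((a - mean(a))^2) + sum((b - mean(b))^2)
    }, numeric(1))
    which.min(cost) + 1
  }
  g_cp <- met$step[changepoint(met$avg_geodesic)]
  expect_lte(abs(g_cp - fs), 5)
  # geodesic averages over the surviving within-subgroup pairs: a drop
  expect_lt(mean(met$avg_geodesic[met$step >= fs]),
            mean(met$avg_geodesic[met$step < fs]))
  # the out-degree entropy shifts level across the split as well
  expect_gt(abs(mean(met$entropy[met$step >= fs]) -
                  mean(met$entropy[met$step < fs])), 0.05)
  # density is blind to the split
  expect_true(all(met$density == 6 / 22))
})
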