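test_that("straightness is 1 on lines, 0 on circles, 2/pi on semicircles", {
  line <- synthetic_trajectory(function(t) {
    cbind(c(0, 3) + 0.1 * t, c(0, 4))
  }, 100)
  expect_equal(straightness(line, c(0, 100)), 1)

  circle <- synthetic_trajectory(function(t) {
    ring_at(1, 5, 2 * pi * t / 360) + 10
  }, 360)
  expect_lt(straightness(circle, c(0, 360)), 0.01)

  semi <- synthetic_trajectory(function(t) {
    ring_at(1, 5, pi * t / 500)
  }, 500)
  expect_equal(straightness(semi, c(0, 500)), 2 / pi, tolerance = 1e-4)
})

test_that("helicity separates rigid rotation from rigid translation", {
  translation <- synthetic_trajectory(function(t) {
    ring_at(6, 3, 0) + 0.2 * t
  }, 50)
  expect_equal(as.numeric(helicity(translation, c(0, 50))), 0)

  rotation <- synthetic_trajectory(function(t) {
    ring_at(6, 3, 0.02 * t)
  }, 50)
  expect_equal(as.numeric(helicity(rotation, c(0, 50))), 1, tolerance = 1e-3)

  # identical per-agent displacements always give zero angular momentum,
  # whatever the shape of the configuration
  set.seed(2)
  blob <- matrix(stats::runif(16, 0, 7), 8, 2)
  drift <- synthetic_trajectory(function(t) {
    sweep(blob, 2, c(0.3, -0.1) * t, "+")
  }, 40)
  expect_equal(as.numeric(helicity(drift, c(0, 40))), 0)
})

test_that("helicity decreases as translation is mixed into rotation", {
  h_for_mix <- function(w) {
    tr <- synthetic_trajectory(function(t) {
      ring_at(6, 3, 0.02 * t) + w * 0.06 * t
    }, 80)
    as.numeric(helicity(tr, c(0, 80)))
  }
  hs <- vapply(c(0, 0.5, 1, 2, 4), h_for_mix, numeric(1))
  expect_true(all(diff(hs) < 0))
  expect_true(all(hs > 0))
  expect_true(all(hs[-1] < 1))
})

test_that("order parameters are invariant under similarity transforms", {
  shape <- function(t) sweep(ring_at(5, 2, 0.03 * t), 2, c(0.05, 0.02) * t, "+")
  base <- synthetic_trajectory(shape, 60)
  s0 <- straightness(base)
  h0 <- helicity(base)
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- synthetic_trajectory(function(t) {
    sweep(3.7 * shape(t) %*% R, 2, c(100, -40), "+")
  }, 60)
  expect_equal(straightness(moved), s0, tolerance = 1e-10)
  expect_equal(helicity(moved), h0, tolerance = 1e-10)
})

test_that("fission detection needs a sustained split", {
  # single tight cluster: one component, no fission step
  pos <- scenario_preformed_subgroups(12, 2, dims = 2, seed = 3)
  one_cluster <- scenario_uniform_cloud(10, dims = 2, spacing = 6, seed = 4)
  g1 <- interaction_graph(one_cluster, 3, step = 0)
  res <- detect_fission(list(g1), window = 1)
  expect_equal(res$n_subgroups, 1)
  expect_true(is.na(res$fission_step))

  # two far clusters of 12 and 11 agents, K = 6: all neighbors in-cluster
  m <- rbind(cbind(stats::runif(12, 0, 15), stats::runif(12, 0, 15)),
             cbind(stats::runif(11, 0, 15) + 100 * 5.2,
                   stats::runif(11, 0, 15)))
  gsplit <- interaction_graph(positions_df(m), 6, step = 0)
  expect_equal(igraph::components(gsplit, mode = "weak")$no, 2)
  graphs <- lapply(0:9, function(s) {
    igraph::set_graph_attr(gsplit, "step", s)
  })
  res <- detect_fission(graphs, window = 5)
  expect_equal(res$fission_step, 0L)
  expect_equal(sort(lengths(res$subgroups)), c(11, 12))
  expect_equal(sort(unlist(res$subgroups)), 0:22)
})

test_that("detected subgroups are each larger than k", {
  # structural consequence: an agent's k nearest lie in its own component
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(12:40, 1)
    k <- sample(2:6, 1)
    m <- matrix(stats::runif(n * 2, 0, 120), n, 2)
    g <- interaction_graph(positions_df(m), k)
    comp <- igraph::components(g, mode = "weak")
    expect_true(all(comp$csize >= k + 1))
  }
})

test_that("classifier labels constructed archetype motions", {
  # rigid straight translation of a ring -> type 1
  tr1 <- synthetic_trajectory(function(t) ring_at(8, 3, 0) + 0.2 * t,
                              200, k = 3)
  b1 <- classify_motion(tr1)
  expect_equal(b1$motion_type, "1")
  expect_gt(b1$straightness, 0.99)
  expect_lt(b1$helicity, 0.05)

  # pure rigid rotation -> orbiting type (5 or 6)
  tr56 <- synthetic_trajectory(function(t) ring_at(8, 3, 0.02 * t),
                               400, k = 3)
  b56 <- classify_motion(tr56)
  expect_true(b56$motion_type %in% c("5", "6"))
  expect_gt(b56$helicity, 0.9)
})

test_that("rapid aggregation at k = N-1 classifies as type 7", {
  traj <- run_swarm(scenario_uniform_cloud(15, seed = 2), 14)
  b <- classify_motion(traj)
  expect_equal(b$motion_type, "7")
  expect_lt(b$straightness, 0.05)
  expect_lt(b$helicity, 0.05)
  expect_false(is.na(traj$stationary_at))
})

test_that("behavior reports tidy into one-row summaries", {
  traj <- run_swarm(scenario_uniform_cloud(8, seed = 1), 3,
                    params = swarm_params(t_max = 400))
  b <- classify_motion(traj)
  td <- tidy(b)
  expect_equal(nrow(td), 1)
  expect_true(all(c("motion_type", "straightness", "helicity",
                    "n_subgroups", "fission_step") %in% names(td)))
  expect_true(td$straightness >= 0 && td$straightness <= 1)
  expect_true(td$helicity >= 0 && td$helicity <= 1)
})
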