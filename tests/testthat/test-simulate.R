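test_that("two-body gap converges to the expected distance", {
  pos <- tibble::tibble(agent_id = 0:1, x = c(0, 6), y = 0, z = 0)
  traj <- run_swarm(pos, k = 1, params = swarm_params(t_max = 5000))
  fin <- dplyr::filter(traj$states, step == max(step))
  gap <- abs(diff(fin$x))
  expect_lt(abs(gap - 5.2), 1e-4)
  expect_false(is.na(traj$stationary_at))
  # gap shrinks monotonically from above
  gaps <- traj$states |>
    dplyr::group_by(step) |>
    dplyr::summarise(g = abs(diff(x)), .groups = "drop")
  expect_true(all(diff(gaps$g) <= 1e-12))
})

test_that("two-body iteration matches the 1-D brute-force oracle", {
  for (x0 in c(2.0, 6.0, 9.5, 20)) {
    pos <- tibble::tibble(agent_id = 0:1, x = c(0, x0), y = 0, z = 0)
    p <- swarm_params(t_max = 200, stability_window = 1000L)
    traj <- run_swarm(pos, k = 1, params = p, stride = 200)
    fin <- dplyr::filter(traj$states, step == max(step))
    expect_equal(abs(diff(fin$x)), oracle_two_body(x0, max(fin$step)),
                 tolerance = 1e-10)
  }
})

test_that("fixed point at d_e is reached from anywhere in (d_l, d_h]", {
  # the run stops once per-step distance changes drop below
  # stability_tol * d_e, leaving a residual of that order near the fixed
  # point; 5e-4 bounds it on both the repulsive and attractive sides
  for (x0 in c(0.5, 3, 5.9, 8.6, 12)) {
    final_gap <- oracle_two_body(x0, 20000)
    expect_lt(abs(final_gap - 5.2), 1e-4)
    pos <- tibble::tibble(agent_id = 0:1, x = c(0, x0), y = 0, z = 0)
    traj <- run_swarm(pos, k = 1, params = swarm_params(t_max = 20000))
    fin <- dplyr::filter(traj$states, step == max(step))
    expect_lt(abs(abs(diff(fin$x)) - 5.2), 5e-4)
  }
})

test_that("compiled run agrees with the pure-R step", {
  set.seed(42)
  for (rep in 1:3) {
    n <- sample(3:12, 1)
    k <- sample(1:(n - 1), 1)
    pos <- positions <- tibble::tibble(
      agent_id = seq_len(n) - 1L,
      x = stats::runif(n, 0, 30), y = stats::runif(n, 0, 30),
      z = stats::runif(n, 0, 30))
    p <- swarm_params(t_max = 5)
    # five R steps
    for (i in 1:5) pos <- swarm_step(pos, k, p)
    traj <- run_swarm(positions, k, p, stride = 5)
    fin <- dplyr::filter(traj$states, step == 5)
    expect_equal(fin$x, pos$x, tolerance = 1e-12)
    expect_equal(fin$y, pos$y, tolerance = 1e-12)
    expect_equal(fin$z, pos$z, tolerance = 1e-12)
  }
})

test_that("step commutes with translation, rotation and relabelling", {
  set.seed(7)
  n <- 10
  k <- 4
  m <- matrix(stats::runif(n * 3, 0, 25), n, 3)
  base <- swarm_step(positions_df(m), k)

  shift <- c(5, -3, 11)
  shifted <- swarm_step(positions_df(sweep(m, 2, -shift)), k)
  expect_equal(as.matrix(shifted[, 2:4]),
               sweep(as.matrix(base[, 2:4]), 2, -shift),
               tolerance = 1e-12, ignore_attr = TRUE)

  R <- random_rotation(3)
  rotated <- swarm_step(positions_df(m %*% R), k)
  expect_equal(as.matrix(rotated[, 2:4]), as.matrix(base[, 2:4]) %*% R,
               tolerance = 1e-9, ignore_attr = TRUE)

  perm <- sample(n)
  relab <- tibble::tibble(agent_id = order(perm) - 1L,
                          x = m[, 1], y = m[, 2], z = m[, 3])
  out <- swarm_step(relab, k)
  # agent originally at row i is now labelled order(perm)[i] - 1
  expect_equal(as.matrix(out[order(perm), 2:4]), as.matrix(base[, 2:4]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("single agents are immediately stationary", {
  one <- tibble::tibble(agent_id = 0L, x = 0, y = 0, z = 0)
  traj <- run_swarm(one, k = 0, params = swarm_params(t_max = 500))
  expect_equal(traj$stationary_at, 0L)
  expect_true(all(traj$states$x == 0))
})

test_that("trajectory bookkeeping is consistent", {
  pos <- scenario_uniform_cloud(8, seed = 5)
  traj <- run_swarm(pos, k = 3, params = swarm_params(t_max = 300), stride = 7)
  expect_equal(traj$centroid$step, 0:traj$n_steps)
  expect_equal(traj$series$step, 0:traj$n_steps)
  steps <- unique(traj$states$step)
  expect_equal(steps[1], 0L)
  expect_equal(max(steps), traj$n_steps)
  expect_true(all(diff(steps) > 0))
  expect_true(all(table(traj$states$step) == 8))
  # stored centroid equals mean of stored positions
  s0 <- dplyr::filter(traj$states, step == max(step))
  expect_equal(unlist(dplyr::filter(traj$centroid,
                                    step == max(step))[, -1]),
               colMeans(as.matrix(s0[, 3:5])), ignore_attr = TRUE)
})

test_that("invalid run requests are rejected", {
  pos <- scenario_uniform_cloud(5, seed = 1)
  expect_error(run_swarm(pos, k = 5), "at most N - 1")
  expect_error(run_swarm(pos, k = 2, params = swarm_params(dims = 2)),
               "dimensional")
  expect_error(swarm_params(t_max = -3), "t_max")
})
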