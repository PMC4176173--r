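test_that("preloading validates exclusion and stall placement", {
  g <- tiny_gene()
  p <- fast_params(footprint = 35L)
  pre <- preload_state(g, 1L, "active", p)
  traj <- run_kmc(g, fast_params(alpha = 0), duration = 0.1, seed = 1,
                  record_interval = 0.02, preload = pre)
  expect_identical(traj$total_initiated, 1)

  expect_error(preload_state(g, c(10L, 20L), "active", p), "exclusion")
  expect_error(preload_state(g, 3L, "stalled", p), "pause site")
  ps <- g$pause_sites[1]
  expect_s3_class(preload_state(g, ps, "stalled", p), "kmc_preload")
})

test_that("an empty lattice with alpha = 0 stays empty", {
  g <- tiny_gene()
  traj <- run_kmc(g, fast_params(alpha = 0), duration = 5, seed = 1)
  expect_identical(traj$total_initiated, 0)
  expect_identical(traj$total_completed, 0)
})

test_that("conservation, exclusion and stall-placement hold on every snapshot", {
  cases <- list(
    list(g = tiny_gene(200, 0.05, 3), p = fast_params(alpha = 2, f = 1)),
    list(g = tiny_gene(200, 0, 3),    p = fast_params(alpha = 5, footprint = 1L)),
    list(g = build_gene(2700, 0.002, 73),
         p = kinetic_params(0.5, 62, f = 4, tau = 15, dt = 0.003)))
  for (seed in c(1, 7)) {
    for (cs in cases) {
      traj <- run_kmc(cs$g, cs$p, duration = 60, seed = seed,
                      record_interval = 2)
      expect_trajectory_invariants(traj)
    }
  }
})

test_that("identical seeds reproduce trajectories exactly; seeds matter", {
  g <- tiny_gene(200, 0.05, 3)
  p <- fast_params(alpha = 1, f = 1)
  a <- run_kmc(g, p, duration = 30, seed = 42)
  b <- run_kmc(g, p, duration = 30, seed = 42)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$completion_times, b$completion_times)
  c <- run_kmc(g, p, duration = 30, seed = 43)
  expect_false(identical(a$snapshots, c$snapshots))
})

test_that("pause-free transit times match the geometric-sum law", {
  g <- build_gene(1000, 0, seed = 1)
  p <- kinetic_params(0, 50, f = 0, tau = 1, dt = 0.002)
  tt <- transit_times(g, p, n_reps = 3000, seed = 5)
  expect_equal(mean(tt), 1000 / 50, tolerance = 0.01)
  p_step <- 50 * 0.002
  expect_equal(var(tt), 1000 * (1 - p_step) / p_step^2 * 0.002^2,
               tolerance = 0.1)
})

test_that("halving the timestep leaves the mean transit time unchanged", {
  g <- build_gene(1000, 0, seed = 1)
  m <- vapply(c(0.002, 0.001), function(dt) {
    mean(transit_times(g, kinetic_params(0, 50, dt = dt), 2000, seed = 9))
  }, numeric(1))
  expect_lt(abs(m[1] - m[2]) / m[1], 0.01)
})

test_that("the random update order preserves all invariants", {
  g <- tiny_gene(200, 0.05, 3)
  p <- fast_params(alpha = 2, f = 1)
  traj <- run_kmc(g, p, duration = 40, seed = 4, update_order = "random",
                  record_interval = 2)
  expect_trajectory_invariants(traj)
  expect_gt(traj$total_completed, 0)
})

test_that("trajectory exports are consistent with the snapshots", {
  g <- tiny_gene(200, 0.02, 3)
  p <- fast_params(alpha = 1, f = 2)
  traj <- run_kmc(g, p, duration = 30, seed = 8, record_interval = 3)
  df <- as.data.frame(traj)
  expect_identical(nrow(df), sum(lengths(traj$snapshots$position)))
  m <- occupancy_matrix(traj)
  expect_identical(dim(m), c(n_snapshots(traj), g$L))
  k <- n_snapshots(traj)
  expect_identical(sum(m[k, ] > 0), length(traj$snapshots$position[[k]]))
  sn <- snapshot(traj, k)
  expect_identical(sn$position, traj$snapshots$position[[k]])
})

test_that("the engine refuses invalid runs", {
  g <- tiny_gene()
  expect_error(run_kmc(g, fast_params(), duration = -1, seed = 1), "duration")
  bad <- fast_params()
  bad$dt <- 0.1  # bypasses the constructor; run_kmc re-validates
  expect_error(run_kmc(g, bad, duration = 1, seed = 1), "timestep")
})
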