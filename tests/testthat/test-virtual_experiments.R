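test_that("the analytic transit oracle evaluates its closed form", {
  expect_equal(analytic_transit_time(100, 0, 50), 2.0)
  expect_equal(analytic_transit_time(100, 5, 50, f = 1, tau = 10), 3.0)
  expect_equal(analytic_transit_time(100, 7, 50, f = 0, tau = 99), 2.0)
  expect_error(analytic_transit_time(100, 0, 0), "epsilon")
})

test_that("the maximal-current bound matches known values and is decreasing", {
  expect_equal(max_current_bound(60, 1), 15)
  expect_equal(max_current_bound(60, 35), 60 / (1 + sqrt(35))^2)
  d <- c(1, 4, 10, 35, 50)
  expect_true(all(diff(max_current_bound(60, d)) < 0))
  expect_error(max_current_bound(60, 0), "d must")
})

test_that("induction signals start at zero, are monotone, early >= late", {
  g <- default_gene()
  p <- kinetic_presets()$nogre_pause_duration
  sig <- simulate_induction(g, apply_scenario(p$params, p$scenario),
                            n_runs = 30, duration = 80, seed = 3)
  expect_equal(sig$early[1], 0)
  expect_equal(sig$late[1], 0)
  expect_true(all(diff(sig$early) >= 0))
  expect_true(all(diff(sig$late) >= 0))
  expect_true(all(sig$early >= sig$late))
})

test_that("without pausing the early and late slopes agree", {
  g <- build_gene(2700, 0, seed = 73)
  p <- kinetic_params(0.3, 62, f = 0, tau = 1, dt = 0.003)
  sig <- simulate_induction(g, p, n_runs = 120, duration = 150, seed = 31)
  expect_equal(signal_slopes(sig)$ratio, 1, tolerance = 0.05)
})

test_that("the velocity estimator is exact on synthetic linear signals", {
  tv <- seq(0, 200, by = 0.5)
  # linear rises with onsets 10 s and 45 s, capped at a shared plateau so
  # both relative-onset detectors see the same end value
  early <- pmin(pmax(0, tv - 10), 100)
  late <- pmin(pmax(0, tv - 45), 100)
  sig <- probe_signal_series(tv, early, late, n_runs = 1,
                             probe_early_end = 500, probe_late_end = 2600)
  v <- estimate_velocity(sig)
  expect_equal(v$velocity, 2100 / 35, tolerance = 1e-6)
  expect_equal(v$onset_early, 10, tolerance = 1e-6)
  expect_equal(v$onset_late, 45, tolerance = 1e-6)
  v2 <- estimate_velocity(sig, method = "threshold")
  expect_equal(v2$velocity, 60, tolerance = 0.01)
})

test_that("a silent promoter yields a no-onset error", {
  g <- default_gene()
  p <- kinetic_presets()$wildtype$params
  p$alpha <- 0
  sig <- simulate_induction(g, p, n_runs = 2, duration = 10, seed = 1)
  expect_error(estimate_velocity(sig), "never rises")
})

test_that("velocity converges to the configured stepping rate", {
  g <- default_gene()
  v <- estimate_velocity(
    simulate_induction(g, kinetic_presets()$wildtype$params,
                       n_runs = 150, seed = 11))
  expect_equal(v$velocity, 62, tolerance = 0.1)
})

test_that("steady-state rate matches alpha in the initiation-limited regime", {
  g <- build_gene(1000, 0, seed = 1)
  p <- kinetic_params(0.01, 60, dt = 0.003)
  res <- steady_state_rate(g, p, n_steps = round(15000 / 0.003), seed = 6)
  expect_equal(res$rate, 0.01, tolerance = 0.05)
  expect_lte(res$rate, max_current_bound(60, 35) * 1.05)
})

test_that("prolonging pauses can only lower the transcription rate", {
  g <- default_gene()
  base <- kinetic_presets()$nogre_pause_duration$params
  slow <- apply_scenario(base, scenario("nogre_pause_duration", 100))
  for (seed in c(2, 12)) {
    r_wt <- suppressWarnings(steady_state_rate(g, base, 2e5, seed = seed)$rate)
    r_sc <- suppressWarnings(steady_state_rate(g, slow, 2e5, seed = seed)$rate)
    expect_lte(r_sc, r_wt * 1.05)
  }
})

test_that("a run with no completions raises the undefined-rate error", {
  g <- default_gene()
  p <- kinetic_presets()$wildtype$params
  expect_error(steady_state_rate(g, p, n_steps = 100, seed = 1),
               "no transcripts completed")
})

test_that("the flux relation links rate, occupancy and mean velocity", {
  g <- default_gene()
  p <- kinetic_presets()$nogre_pause_duration$params
  p$alpha <- 0.8
  res <- steady_state_rate(g, apply_scenario(p, scenario("nogre_pause_duration", 100)),
                           n_steps = 4e5, burn_in_fraction = 0.25, seed = 5)
  expect_equal(res$rate * g$L / res$mean_velocity, res$mean_occupancy,
               tolerance = 0.1)
})

test_that("queue sizes are read off a configuration correctly", {
  # stalled leader at 500 with two followers packed at spacing d = 35
  expect_identical(
    queue_sizes(c(500, 465, 430), c(1, 0, 0), 35), 2L)
  # lone complex, active or stalled, forms no queue of positive size
  expect_identical(queue_sizes(600, 0, 35), integer(0))
  expect_identical(queue_sizes(600, 1, 35), 0L)
  # gap breaks the run
  expect_identical(queue_sizes(c(500, 465, 420), c(1, 0, 0), 35), 1L)
  # stalled member mid-run: queue counted behind the most downstream stalled
  expect_identical(queue_sizes(c(500, 465, 430), c(0, 1, 0), 35), 1L)
})

test_that("queues appear behind forced stalls and never without stalling", {
  g <- tiny_gene(300, 0.02, 4)
  p <- fast_params(alpha = 3, epsilon = 50, f = 0, footprint = 10L)
  traj <- run_kmc(g, p, duration = 60, seed = 9, record_interval = 2)
  qs <- queue_statistics(traj)
  expect_identical(qs$fraction_snapshots_with_queue, 0)

  # rescue practically switched off: one stall jams the gene
  pj <- kinetic_params(3, 50, f = 5, tau = 500, footprint = 10L, dt = 0.002)
  traj <- run_kmc(g, pj, duration = 120, seed = 9, record_interval = 2)
  qs <- queue_statistics(traj)
  expect_gt(qs$fraction_snapshots_with_queue, 0.5)
  expect_gt(qs$max_queue_size, 3)
})

test_that("wildtype-vs-wildtype sweeps give unit fold change", {
  g <- default_gene()
  p <- kinetic_presets()$wildtype$params
  tab <- sweep_alpha(g, p, scenario("wildtype", 1), alpha_grid = c(0.05, 0.3),
                     n_steps = 2e5, n_reps = 4, seed = 3)
  expect_identical(nrow(tab), 2L)
  expect_true(all(abs(tab$fold_change - 1) < 3 * tab$fold_se + 0.05))
})

test_that("pause-free genes show unit fold change at any length", {
  p <- kinetic_presets()$nogre_pause_duration$params
  tab <- sweep_length(p, scenario("nogre_pause_duration", 100),
                      L_grid = c(600, 1800), pause_density = 0,
                      n_steps = 2e5, n_reps = 3, seed = 3)
  expect_true(all(abs(tab$fold_change - 1) < 3 * tab$fold_se + 0.05))
  expect_true(all(diff(tab$rate_wt) < 0.05))  # saturates, never grows
})
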