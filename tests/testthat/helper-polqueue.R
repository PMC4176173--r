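# shared fixtures and invariant checkers (everything built in code)

tiny_gene <- function(L = 100, density = 0.05, seed = 2) {
  build_gene(L, pause_density = density, seed = seed)
}

fast_params <- function(alpha = 0.2, epsilon = 50, f = 0, tau = 1,
                        footprint = 10L, dt = 0.002) {
  kinetic_params(alpha, epsilon, f, tau, footprint, dt)
}

# conservation, exclusion, bounds and stalled-on-pause-site, on every snapshot
expect_trajectory_invariants <- function(traj) {
  d <- traj$params$footprint
  pauses <- traj$gene$pause_sites
  for (k in seq_len(n_snapshots(traj))) {
    p <- traj$snapshots$position[[k]]
    s <- traj$snapshots$state[[k]]
    expect_identical(traj$initiated[k] - traj$completed[k], length(p))
    expect_true(all(p >= 1 & p <= traj$gene$L))
    if (length(p) > 1) expect_true(all(-diff(p) >= d))
    if (any(s == 1)) expect_true(all(p[s == 1] %in% pauses))
  }
  expect_true(all(diff(traj$completed) >= 0))
}

# a reference sequence with a known homopolymer-free / homopolymer-rich mix
# is built per test where needed; no fixture files are stored
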