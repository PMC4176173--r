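#' Preload a lattice configuration
#'
#' Builds a validated starting state for [run_kmc()]: a set of elongation
#' complexes already on the gene, used e.g. for single-complex transit-time
#' measurements. Positions must respect hard exclusion (mutual spacing of at
#' least the footprint) and stalled complexes must sit on pause sites.
#'
#' @param gene A `gene_model`.
#' @param positions Integer active-site positions in `[1, L]`.
#' @param states Character (`"active"`/`"stalled"`) or integer (0/1) states,
#'   recycled if length 1.
#' @param params A `kinetic_params` (supplies the footprint).
#' @return Object of class `kmc_preload` (positions sorted downstream-first).
#' @export
preload_state <- function(gene, positions, states = "active", params) {
  stopifnot(inherits(gene, "gene_model"), inherits(params, "kinetic_params"))
  positions <- as.integer(positions)
  if (length(positions) == 0L)
    return(structure(list(positions = integer(0), states = integer(0)),
                     class = "kmc_preload"))
  if (any(positions < 1L | positions > gene$L))
    stop("preload positions must lie in [1, L]")
  if (is.character(states))
    states <- match(states, c("active", "stalled")) - 1L
  states <- as.integer(rep_len(states, length(positions)))
  if (any(is.na(states) | !(states %in% c(0L, 1L))))
    stop("states must be 'active'/'stalled' (or 0/1)")
  o <- order(positions, decreasing = TRUE)
  positions <- positions[o]; states <- states[o]
  if (anyDuplicated(positions) ||
      (length(positions) > 1L &&
       any(-diff(positions) < params$footprint)))
    stop("preload violates exclusion: positions closer than the footprint")
  if (any(states == 1L & !(positions %in% gene$pause_sites)))
    stop("a stalled complex must sit on a pause site")
  structure(list(positions = positions, states = states),
            class = "kmc_preload")
}

#' Run the kinetic Monte Carlo elongation simulation
#'
#' Simulates stochastic steppers with hard exclusion on the gene lattice with
#' a fixed timestep. Within one timestep complexes are updated from the most
#' downstream to the most upstream (so a step never reacts to a same-step
#' move of an upstream neighbour); a stalled complex is rescued with
#' probability `dt/tau`; an active complex on a pause site first stalls with
#' probability `f*dt` and otherwise attempts a forward step with probability
#' `epsilon*dt`; steps into another complex's footprint are rejected; a
#' complex whose active site passes `L` terminates. Initiation is attempted
#' last: if sites `1..footprint` are free, a new complex enters at site 1
#' with probability `alpha*dt`.
#'
#' Identical `(gene, params, seed, ...)` give the identical trajectory.
#'
#' @param gene A `gene_model`.
#' @param params A `kinetic_params`; must pass [validate_params()].
#' @param duration Simulated time (s). Alternatively give `n_steps`.
#' @param n_steps Number of timesteps (overrides `duration`).
#' @param seed Integer RNG seed.
#' @param record_interval Time between recorded snapshots (s).
#' @param preload Optional `kmc_preload` starting configuration.
#' @param update_order `"downstream"` (default) or `"random"` (per-step
#'   random permutation, for update-order sensitivity checks).
#' @param record_snapshots Keep full per-snapshot configurations (needed for
#'   queue statistics and kymographs). Probe-signal and counter series are
#'   always recorded.
#' @param stat_start_time Time (s) after which the flux counters
#'   (accepted steps, complex-time on the lattice, post-burn-in completions)
#'   accumulate; used by [steady_state_rate()].
#' @return Object of class `kmc_trajectory`.
#' @export
run_kmc <- function(gene, params, duration = NULL, n_steps = NULL, seed = 1L,
                    record_interval = 1, preload = NULL,
                    update_order = c("downstream", "random"),
                    record_snapshots = TRUE, stat_start_time = 0) {
  stopifnot(inherits(gene, "gene_model"))
  validate_params(params)
  update_order <- match.arg(update_order)
  if (is.null(n_steps)) {
    if (is.null(duration) || duration <= 0)
      stop("give a positive duration or n_steps")
    n_steps <- as.integer(round(duration / params$dt))
  }
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("simulation must span at least one timestep")
  record_every <- max(1L, as.integer(round(record_interval / params$dt)))
  if (is.null(preload))
    preload <- structure(list(positions = integer(0), states = integer(0)),
                         class = "kmc_preload")
  stopifnot(inherits(preload, "kmc_preload"))

  set.seed(as.integer(seed))
  raw <- cpp_kmc_run(
    L = gene$L, pause_sites = as.integer(gene$pause_sites),
    alpha = params$alpha, epsilon = params$epsilon,
    f = params$f, tau = params$tau,
    d = params$footprint, dt = params$dt, n_steps = n_steps,
    record_every = record_every, keep_snapshots = record_snapshots,
    init_pos = preload$positions, init_state = preload$states,
    random_order = (update_order == "random"),
    probe_early_end = gene$probe_early[2], probe_late_end = gene$probe_late[2],
    stat_start_step = as.integer(round(stat_start_time / params$dt)))

  structure(
    list(gene = gene, params = params, seed = as.integer(seed),
         n_steps = n_steps, dt = params$dt,
         time = raw$time, initiated = raw$initiated,
         completed = raw$completed, n_on_lattice = raw$n_on_lattice,
         early = raw$early, late = raw$late,
         snapshots = raw$snapshots,
         completion_times = raw$completion_times,
         total_initiated = raw$total_initiated,
         total_completed = raw$total_completed,
         completed_post = raw$completed_post,
         steps_accepted = raw$steps_accepted,
         ec_time = raw$ec_time,
         final = list(position = raw$final_position,
                      state = raw$final_state, id = raw$final_id)),
    class = "kmc_trajectory")
}

#' @export
print.kmc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<kmc_trajectory> %d steps (dt=%.4g s); initiated %d, completed %d, on lattice %d\n",
    x$n_steps, x$dt, x$total_initiated, x$total_completed,
    length(x$final$position)))
  invisible(x)
}

#' Number of recorded snapshots in a trajectory
#' @param traj A `kmc_trajectory`.
#' @return Integer count.
#' @export
n_snapshots <- function(traj) length(traj$time)

#' Extract one recorded snapshot
#'
#' @param traj A `kmc_trajectory` run with `record_snapshots = TRUE`.
#' @param k Snapshot index (1-based).
#' @return Data frame with columns `id`, `position`, `state`
#'   (`"active"`/`"stalled"`), ordered downstream-first.
#' @export
snapshot <- function(traj, k) {
  if (is.null(traj$snapshots)) stop("trajectory was run without snapshots")
  data.frame(
    id = traj$snapshots$id[[k]],
    position = traj$snapshots$position[[k]],
    state = c("active", "stalled")[traj$snapshots$state[[k]] + 1L])
}

#' Flatten a trajectory to a long table
#'
#' One row per (snapshot, complex): `time`, `id`, `position`, `state`. This
#' is the tabular trajectory export.
#'
#' @param x A `kmc_trajectory`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.kmc_trajectory <- function(x, ...) {
  if (is.null(x$snapshots)) stop("trajectory was run without snapshots")
  n <- lengths(x$snapshots$position)
  data.frame(
    time = rep(x$time, n),
    id = unlist(x$snapshots$id),
    position = unlist(x$snapshots$position),
    state = c("active", "stalled")[unlist(x$snapshots$state) + 1L])
}

#' Dense occupancy matrix for kymograph rendering
#'
#' @param traj A `kmc_trajectory` with snapshots.
#' @return Integer matrix (snapshots x sites): 0 empty, 1 active-site of an
#'   active complex, 2 active-site of a stalled complex. Row names are
#'   snapshot times.
#' @export
occupancy_matrix <- function(traj) {
  if (is.null(traj$snapshots)) stop("trajectory was run without snapshots")
  m <- matrix(0L, nrow = n_snapshots(traj), ncol = traj$gene$L,
              dimnames = list(format(traj$time), NULL))
  for (k in seq_len(n_snapshots(traj))) {
    p <- traj$snapshots$position[[k]]
    s <- traj$snapshots$state[[k]]
    m[k, p] <- s + 1L
  }
  m
}
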