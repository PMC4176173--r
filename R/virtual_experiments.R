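#' Closed-form mean single-complex transit time
#'
#' For a lone complex (no exclusion), transit over `L` sites at stepping rate
#' `epsilon` with `n_pause` pause sites (stall rate `f`, mean stall duration
#' `tau`) takes on average `(L + n_pause * f * tau) / epsilon` seconds: each
#' pause site contributes a mean of `f/epsilon` stall events of mean length
#' `tau`. Serves as the analytic oracle for the simulation engine.
#'
#' @param L Sites to traverse.
#' @param n_pause Number of pause sites.
#' @param epsilon Stepping rate (nt/s), positive.
#' @param f Stall rate (1/s).
#' @param tau Mean stall duration (s).
#' @return Mean transit time in seconds.
#' @export
analytic_transit_time <- function(L, n_pause, epsilon, f = 0, tau = 0) {
  if (epsilon <= 0) stop("epsilon must be positive")
  (L + n_pause * f * tau) / epsilon
}

#' Maximal-current bound for extended steppers
#'
#' The steady-state throughput of an exclusion process of particles with
#' footprint `d` and stepping rate `epsilon` cannot exceed
#' `epsilon / (1 + sqrt(d))^2`; for `d = 1` this is the classic `epsilon/4`.
#'
#' @param epsilon Stepping rate (nt/s).
#' @param d Footprint (sites), at least 1.
#' @return Transcripts per second.
#' @export
max_current_bound <- function(epsilon, d) {
  if (any(d < 1)) stop("d must be >= 1")
  epsilon / (1 + sqrt(d))^2
}

#' Measure single-complex transit times by simulation
#'
#' Runs `n_reps` independent simulations, each starting from one active
#' complex preloaded at the transcription start with initiation switched
#' off, and returns the completion times. Replicate `r` uses seed
#' `seed + r - 1`.
#'
#' @param gene A `gene_model`.
#' @param params A `kinetic_params` (`alpha` is ignored and forced to 0).
#' @param n_reps Number of replicates.
#' @param seed Base seed.
#' @return Numeric vector of transit times (s).
#' @export
transit_times <- function(gene, params, n_reps, seed = 1L) {
  p0 <- params
  p0$alpha <- 0
  expect <- analytic_transit_time(gene$L, length(gene$pause_sites),
                                  params$epsilon, params$f, params$tau)
  duration <- 2 * expect + 30 * params$tau + 10
  pre <- preload_state(gene, 1L, "active", p0)
  out <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    traj <- run_kmc(gene, p0, duration = duration, seed = seed + r - 1L,
                    record_interval = duration, preload = pre,
                    record_snapshots = FALSE)
    out[r] <- if (length(traj$completion_times)) traj$completion_times[1] else NA_real_
  }
  if (anyNA(out)) warning(sum(is.na(out)), " replicate(s) did not complete")
  out
}

#' Construct a probe-signal series
#'
#' Run-averaged cumulative counts of transcripts that have been extended
#' past the early and late probe windows' 3' ends, as a function of time
#' since induction. Both signals must be non-decreasing and the early signal
#' must dominate the late one pointwise (a transcript passes the early probe
#' before the late one).
#'
#' @param time Snapshot times (s).
#' @param early,late Mean cumulative counts.
#' @param n_runs Number of replicate runs averaged.
#' @param probe_early_end,probe_late_end 3' end sites of the probe windows.
#' @return Object of class `probe_signal_series`.
#' @export
probe_signal_series <- function(time, early, late, n_runs,
                                probe_early_end, probe_late_end) {
  stopifnot(length(time) == length(early), length(early) == length(late))
  if (any(diff(early) < -1e-9) || any(diff(late) < -1e-9))
    stop("probe signals must be non-decreasing")
  if (any(late > early + 1e-9))
    stop("late signal cannot exceed early signal")
  structure(
    list(time = time, early = early, late = late, n_runs = n_runs,
         probe_early_end = probe_early_end, probe_late_end = probe_late_end),
    class = "probe_signal_series")
}

#' @export
print.probe_signal_series <- function(x, ...) {
  cat(sprintf(
    "<probe_signal_series> %d timepoints over %.1f s, mean of %d run(s); final early %.2f / late %.2f\n",
    length(x$time), max(x$time), x$n_runs,
    x$early[length(x$early)], x$late[length(x$late)]))
  invisible(x)
}

#' @export
as.data.frame.probe_signal_series <- function(x, ...) {
  data.frame(time = x$time, early = x$early, late = x$late)
}

#' Simulate an induction (two-probe) experiment
#'
#' Every replicate run starts from an empty lattice at `t = 0` (induction)
#' and records, on a common time grid, the cumulative number of transcripts
#' whose active site has passed each probe window's 3' end (completed
#' transcripts stay counted). Signals are averaged over `n_runs` replicates;
#' replicate `r` uses seed `seed + r - 1`.
#'
#' @param gene A `gene_model` with probe windows.
#' @param params A `kinetic_params`.
#' @param n_runs Replicate runs (>= 1).
#' @param duration Simulated induction window (s).
#' @param seed Base seed.
#' @param record_interval Signal sampling interval (s).
#' @return A [probe_signal_series()].
#' @export
simulate_induction <- function(gene, params, n_runs = 1000, duration = 150,
                               seed = 1L, record_interval = 0.5) {
  stopifnot(inherits(gene, "gene_model"))
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (is.null(gene$probe_early) || is.null(gene$probe_late))
    stop("gene has no probe windows")
  early <- late <- NULL
  tv <- NULL
  for (r in seq_len(n_runs)) {
    traj <- run_kmc(gene, params, duration = duration, seed = seed + r - 1L,
                    record_interval = record_interval,
                    record_snapshots = FALSE)
    if (is.null(early)) {
      tv <- traj$time
      early <- as.numeric(traj$early)
      late <- as.numeric(traj$late)
    } else {
      early <- early + traj$early
      late <- late + traj$late
    }
  }
  probe_signal_series(tv, early / n_runs, late / n_runs, n_runs,
                      gene$probe_early[2], gene$probe_late[2])
}

.signal_onset <- function(tv, sv, method, fit_range, threshold) {
  end_val <- sv[length(sv)]
  if (end_val <= 0) stop("signal never rises: no onset can be located")
  if (method == "fit") {
    sel <- sv >= fit_range[1] * end_val & sv <= fit_range[2] * end_val
    if (sum(sel) < 2L)
      stop("fewer than two points in the rising phase; record more finely")
    b <- coef(lm(y ~ x, data = data.frame(x = tv[sel], y = sv[sel])))
    if (!is.finite(b[2]) || b[2] <= 0) stop("rising phase has no positive slope")
    unname(-b[1] / b[2])
  } else {
    thr <- threshold * end_val
    i <- which(sv >= thr)[1]
    if (is.na(i)) stop("signal never crosses the onset threshold")
    if (i == 1L) return(tv[1])
    # linear interpolation between the bracketing samples
    tv[i - 1] + (thr - sv[i - 1]) / (sv[i] - sv[i - 1]) * (tv[i] - tv[i - 1])
  }
}

#' Two-probe elongation velocity estimator
#'
#' Estimates the elongation velocity as the distance between the probe
#' windows' 3' ends divided by the difference between the onset times of the
#' late and early signals. The default onset detector fits a straight line
#' to each signal's rising phase (points between 10% and 50% of its value at
#' the end of the series) and takes the x-intercept; a simple
#' threshold-crossing detector is available as an alternative.
#'
#' @param signals A `probe_signal_series`.
#' @param gene Optional `gene_model`; only needed if `signals` lacks the
#'   probe end positions.
#' @param method `"fit"` (default) or `"threshold"`.
#' @param fit_range Rising-phase bounds as fractions of the end value.
#' @param threshold Crossing fraction for `method = "threshold"`.
#' @return Object of class `velocity_estimate` with fields `velocity`
#'   (nt/s), `onset_early`, `onset_late` (s) and `probe_distance` (nt).
#' @export
estimate_velocity <- function(signals, gene = NULL,
                              method = c("fit", "threshold"),
                              fit_range = c(0.1, 0.5), threshold = 0.05) {
  stopifnot(inherits(signals, "probe_signal_series"))
  method <- match.arg(method)
  e_end <- signals$probe_early_end
  l_end <- signals$probe_late_end
  if ((is.null(e_end) || is.null(l_end)) && !is.null(gene)) {
    e_end <- gene$probe_early[2]; l_end <- gene$probe_late[2]
  }
  if (is.null(e_end) || is.null(l_end))
    stop("probe end positions unavailable; pass the gene")
  onset_early <- .signal_onset(signals$time, signals$early, method,
                               fit_range, threshold)
  onset_late <- .signal_onset(signals$time, signals$late, method,
                              fit_range, threshold)
  if (onset_late <= onset_early)
    stop("late onset does not follow the early onset")
  dist <- l_end - e_end
  structure(
    list(velocity = dist / (onset_late - onset_early),
         onset_early = onset_early, onset_late = onset_late,
         probe_distance = dist, method = method),
    class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf(
    "<velocity_estimate> %.1f nt/s (probe distance %d nt; onsets %.1f s / %.1f s)\n",
    x$velocity, x$probe_distance, x$onset_early, x$onset_late))
  invisible(x)
}

#' Asymptotic slopes of the probe signals
#'
#' Fits straight lines to the tail of each signal (the last
#' `tail_fraction` of the simulated window) and returns the slopes and
#' their late/early ratio. Equal slopes mean every transcript that passes
#' the early probe also reaches the late probe within the window; a reduced
#' ratio is the signature of long-lived pausing.
#'
#' @param signals A `probe_signal_series`.
#' @param tail_fraction Fraction of the window used for the fit.
#' @return List with `early`, `late` (counts/s) and `ratio` (late/early).
#' @export
signal_slopes <- function(signals, tail_fraction = 0.4) {
  stopifnot(inherits(signals, "probe_signal_series"))
  t0 <- max(signals$time) - tail_fraction * diff(range(signals$time))
  sel <- signals$time >= t0
  if (sum(sel) < 3L) stop("too few points in the slope window")
  sl <- function(sv) unname(coef(lm(y ~ x, data = data.frame(
    x = signals$time[sel], y = sv[sel])))[2])
  early <- sl(signals$early); late <- sl(signals$late)
  list(early = early, late = late, ratio = late / early)
}

#' Steady-state transcription rate and lattice statistics
#'
#' Runs one long simulation, discards a burn-in, and reports the
#' transcription rate (completed transcripts per second after burn-in), the
#' mean number of complexes on the gene, the mean on-gene velocity
#' (accepted steps per complex-second, pauses and queuing included), and
#' queue statistics.
#'
#' @param gene A `gene_model`.
#' @param params A `kinetic_params`.
#' @param n_steps Total timesteps; should give at least ~100 completions
#'   after burn-in (warned otherwise).
#' @param burn_in_fraction Fraction of the run discarded.
#' @param seed RNG seed.
#' @param queue_stats Collect snapshots and queue statistics (slower).
#' @param record_interval Snapshot spacing (s); defaults to 1/400 of the
#'   post-burn-in window.
#' @return Object of class `steady_state_result` with `rate`,
#'   `mean_occupancy`, `mean_velocity`, `n_completions`, `elapsed` and
#'   (optionally) `queue_stats`.
#' @export
steady_state_rate <- function(gene, params, n_steps, burn_in_fraction = 0.1,
                              seed = 1L, queue_stats = FALSE,
                              record_interval = NULL) {
  stopifnot(n_steps >= 10)
  burn_steps <- round(n_steps * burn_in_fraction)
  elapsed <- (n_steps - burn_steps) * params$dt
  if (is.null(record_interval))
    record_interval <- max(params$dt, elapsed / 400)
  traj <- run_kmc(gene, params, n_steps = n_steps, seed = seed,
                  record_interval = record_interval,
                  record_snapshots = queue_stats,
                  stat_start_time = burn_steps * params$dt)
  n_comp <- traj$completed_post
  if (n_comp == 0)
    stop(sprintf(
      "no transcripts completed after burn-in (alpha=%.3g, %d steps); extend the run",
      params$alpha, n_steps))
  if (n_comp < 100)
    warning("only ", n_comp,
            " completions after burn-in; the rate estimate will be noisy")
  qs <- NULL
  if (queue_stats) {
    post <- traj$time > burn_steps * params$dt
    qs <- queue_statistics(traj, which_snapshots = which(post))
  }
  structure(
    list(rate = n_comp / elapsed,
         mean_occupancy = traj$ec_time / elapsed,
         mean_velocity = if (traj$ec_time > 0)
           traj$steps_accepted / traj$ec_time else NA_real_,
         n_completions = n_comp, elapsed = elapsed,
         queue_stats = qs, params = params, seed = seed),
    class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf(
    "<steady_state_result> rate %.4g /s; occupancy %.2f; mean velocity %.1f nt/s (%d completions over %.0f s)\n",
    x$rate, x$mean_occupancy, x$mean_velocity, x$n_completions, x$elapsed))
  invisible(x)
}

#' Queue ("traffic jam") sizes in one lattice configuration
#'
#' A queue is a maximal run of complexes at mutual spacing exactly equal to
#' the footprint packed behind a stalled complex; its size is the number of
#' complexes upstream of the most downstream stalled member of the run. A
#' stalled complex with no packed follower has queue size 0.
#'
#' @param positions Active-site positions, any order.
#' @param states Integer 0 (active) / 1 (stalled), or `"active"`/`"stalled"`.
#' @param d Footprint (sites).
#' @return Integer vector of queue sizes, one per stalled run (possibly
#'   empty).
#' @export
queue_sizes <- function(positions, states, d) {
  if (is.character(states))
    states <- match(states, c("active", "stalled")) - 1L
  o <- order(positions, decreasing = TRUE)
  p <- as.integer(positions[o]); s <- as.integer(states[o])
  n <- length(p)
  sizes <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && p[j] - p[j + 1L] == d) j <- j + 1L
    st <- which(s[i:j] == 1L)
    if (length(st)) sizes <- c(sizes, j - (i + st[1L] - 1L))
    i <- j + 1L
  }
  sizes
}

#' Queue statistics over a trajectory
#'
#' Scans recorded snapshots for queues (see [queue_sizes()]) and summarizes
#' them: a size histogram, the mean and maximum size of observed queues
#' (complexes packed behind a stalled complex), and the fraction of
#' snapshots containing at least one queue.
#'
#' @param traj A `kmc_trajectory` run with snapshots (>= 2 recorded).
#' @param d Footprint; defaults to the trajectory's.
#' @param which_snapshots Optional snapshot indices to restrict to.
#' @return List with `size_histogram` (named counts of sizes >= 1),
#'   `mean_queue_size`, `max_queue_size`, `fraction_snapshots_with_queue`
#'   and `n_snapshots`.
#' @export
queue_statistics <- function(traj, d = NULL, which_snapshots = NULL) {
  if (is.null(traj$snapshots)) stop("trajectory was run without snapshots")
  if (is.null(d)) d <- traj$params$footprint
  ks <- if (is.null(which_snapshots)) seq_len(n_snapshots(traj)) else which_snapshots
  if (length(ks) < 2L) stop("need at least two snapshots")
  all_sizes <- integer(0)
  with_queue <- 0L
  for (k in ks) {
    sz <- queue_sizes(traj$snapshots$position[[k]],
                      traj$snapshots$state[[k]], d)
    sz <- sz[sz >= 1L]
    if (length(sz)) {
      with_queue <- with_queue + 1L
      all_sizes <- c(all_sizes, sz)
    }
  }
  list(
    size_histogram = if (length(all_sizes)) table(all_sizes) else table(integer(0)),
    mean_queue_size = if (length(all_sizes)) mean(all_sizes) else 0,
    max_queue_size = if (length(all_sizes)) max(all_sizes) else 0L,
    fraction_snapshots_with_queue = with_queue / length(ks),
    n_snapshots = length(ks))
}

.rate_reps <- function(gene, params, n_steps, n_reps, burn_in_fraction,
                       seed_base) {
  vapply(seq_len(n_reps), function(r) {
    suppressWarnings(
      steady_state_rate(gene, params, n_steps, burn_in_fraction,
                        seed = seed_base + r)$rate)
  }, numeric(1))
}

.boot_fold <- function(wt, sc, n_boot, seed) {
  set.seed(seed)
  n <- length(wt)
  fb <- vapply(seq_len(n_boot), function(b) {
    mean(wt[sample.int(n, n, replace = TRUE)]) /
      mean(sc[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  c(se = sd(fb), lo = unname(quantile(fb, 0.025)),
    hi = unname(quantile(fb, 0.975)))
}

#' Expression-level sweep: transcription rate vs initiation rate
#'
#' For each initiation attempt rate in `alpha_grid`, measures the
#' steady-state transcription rate with and without the scenario
#' perturbation and reports the fold change `rate_wt / rate_scenario`
#' (values above 1 mean expression is reduced in the Gre-less condition).
#' Replicate runs give a bootstrap CI on the fold change.
#'
#' @param gene A `gene_model`.
#' @param base_params Wild-type `kinetic_params` (its `alpha` is replaced by
#'   the grid values).
#' @param s A `gre_scenario`.
#' @param alpha_grid Positive, ascending initiation rates (1/s).
#' @param n_steps Steps per run; `NULL` (default) scales the run length so
#'   each replicate expects ~`target_completions` completions.
#' @param n_reps Replicate runs per condition.
#' @param burn_in_fraction Burn-in fraction.
#' @param seed Base seed.
#' @param n_boot Bootstrap resamples for the fold-change CI.
#' @param target_completions Desired completions per replicate when
#'   `n_steps` is automatic.
#' @return Data frame with one row per alpha: `alpha`, `rate_wt`,
#'   `rate_scenario`, `fold_change`, `log2_fold_change`, `fold_se`,
#'   `fold_lo`, `fold_hi`, `n_reps`.
#' @export
sweep_alpha <- function(gene, base_params, s, alpha_grid, n_steps = NULL,
                        n_reps = 6, burn_in_fraction = 0.1, seed = 1L,
                        n_boot = 200, target_completions = 150) {
  stopifnot(inherits(s, "gre_scenario"))
  if (any(alpha_grid <= 0) || is.unsorted(alpha_grid, strictly = TRUE))
    stop("alpha_grid must be positive and strictly ascending")
  rows <- lapply(seq_along(alpha_grid), function(ai) {
    a <- alpha_grid[ai]
    p_wt <- base_params; p_wt$alpha <- a
    validate_params(p_wt)
    p_sc <- apply_scenario(p_wt, s)
    ns <- n_steps
    if (is.null(ns)) {
      t_need <- target_completions / (a * (1 - burn_in_fraction))
      ns <- min(3e6, max(2e5, round(t_need / base_params$dt)))
    }
    sb <- as.integer(seed + 10000 * ai)
    wt <- .rate_reps(gene, p_wt, ns, n_reps, burn_in_fraction, sb)
    sc <- .rate_reps(gene, p_sc, ns, n_reps, burn_in_fraction, sb + 5000L)
    bt <- .boot_fold(wt, sc, n_boot, sb + 9999L)
    data.frame(alpha = a, rate_wt = mean(wt), rate_scenario = mean(sc),
               fold_change = mean(wt) / mean(sc),
               log2_fold_change = log2(mean(wt) / mean(sc)),
               fold_se = bt["se"], fold_lo = bt["lo"], fold_hi = bt["hi"],
               n_reps = n_reps, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Gene-length sweep: fold change vs gene length
#'
#' Like [sweep_alpha()], but varies the gene length at a fixed pause density
#' (so the number of pause sites scales with length) and a fixed initiation
#' rate taken from `base_params`.
#'
#' @param base_params Wild-type `kinetic_params`.
#' @param s A `gre_scenario`.
#' @param L_grid Ascending gene lengths (nt).
#' @param pause_density Pause sites per nt, shared by all lengths.
#' @param n_steps Steps per run (fixed; long genes need long runs).
#' @param n_reps Replicates per condition.
#' @param burn_in_fraction Burn-in fraction.
#' @param seed Base seed for the runs.
#' @param gene_seed Base seed for the pause-site draws; replicate `r` of
#'   every length uses layout seed `gene_seed + r`.
#' @param n_boot Bootstrap resamples.
#' @return Data frame as in [sweep_alpha()], with column `L` instead of
#'   `alpha`.
#' @export
sweep_length <- function(base_params, s, L_grid, pause_density = 0.002,
                         n_steps = 6e5, n_reps = 4, burn_in_fraction = 0.1,
                         seed = 1L, gene_seed = 73L, n_boot = 200) {
  stopifnot(inherits(s, "gre_scenario"))
  if (is.unsorted(L_grid, strictly = TRUE)) stop("L_grid must be ascending")
  p_sc <- apply_scenario(base_params, s)
  rows <- lapply(seq_along(L_grid), function(li) {
    sb <- as.integer(seed + 20000 * li)
    # one independent pause-site layout per replicate, shared by both arms,
    # so the length effect is averaged over layouts rather than tied to one
    wt <- sc <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      g <- build_gene(L_grid[li], pause_density, gene_seed + r)
      wt[r] <- suppressWarnings(steady_state_rate(
        g, base_params, n_steps, burn_in_fraction, seed = sb + r)$rate)
      sc[r] <- suppressWarnings(steady_state_rate(
        g, p_sc, n_steps, burn_in_fraction, seed = sb + 5000L + r)$rate)
    }
    bt <- .boot_fold(wt, sc, n_boot, sb + 9999L)
    data.frame(L = L_grid[li], rate_wt = mean(wt), rate_scenario = mean(sc),
               fold_change = mean(wt) / mean(sc),
               log2_fold_change = log2(mean(wt) / mean(sc)),
               fold_se = bt["se"], fold_lo = bt["lo"], fold_hi = bt["hi"],
               n_reps = n_reps, row.names = NULL)
  })
  do.call(rbind, rows)
}
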