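.run_kinds <- c("induction", "sweep-alpha", "sweep-length", "steady-state",
                "fidelity-sim", "fidelity-run")

.gene_from_cfg <- function(g) {
  layout <- if (!is.null(g$probe_layout)) as.numeric(g$probe_layout)
            else c(500 / 2700, 2201 / 2700)
  build_gene(g$L, g$pause_density, g$seed, probe_layout = layout)
}

.params_from_cfg <- function(p) {
  kinetic_params(p$alpha, p$epsilon,
                 f = if (is.null(p$f)) 0 else p$f,
                 tau = if (is.null(p$tau)) 1 else p$tau,
                 footprint = if (is.null(p$footprint)) 35L else p$footprint,
                 dt = if (is.null(p$dt)) 0.01 else p$dt)
}

.scenario_from_cfg <- function(s) {
  if (is.null(s)) scenario("wildtype", 1) else scenario(s$name, s$factor)
}

#' Validate a run configuration
#'
#' Checks a configuration list against the schema before any computation:
#' a known experiment `kind`, an integer `seed`, and the blocks that kind
#' requires (`gene`/`params` for the simulation kinds, `reference`/`reads`/
#' `error_model` for read simulation, `fastq`/`reference` paths for a
#' pipeline run).
#'
#' @param cfg Configuration list (e.g. from [read_run_config()]).
#' @return `cfg`, invisibly; errors with a message otherwise.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$kind) || !(cfg$kind %in% .run_kinds))
    stop("unknown experiment kind: ", deparse(cfg$kind),
         " (expected one of ", paste(.run_kinds, collapse = ", "), ")")
  need <- function(block, fields) {
    if (is.null(cfg[[block]]))
      stop("config for '", cfg$kind, "' needs a '", block, "' block")
    miss <- setdiff(fields, names(cfg[[block]]))
    if (length(miss))
      stop("'", block, "' block is missing: ", paste(miss, collapse = ", "))
  }
  sim_kinds <- c("induction", "sweep-alpha", "sweep-length", "steady-state")
  if (cfg$kind %in% sim_kinds) {
    if (cfg$kind != "sweep-length") need("gene", c("L", "pause_density", "seed"))
    need("params", c("alpha", "epsilon"))
  }
  if (cfg$kind == "sweep-alpha" && is.null(cfg$alpha_grid))
    stop("sweep-alpha needs an 'alpha_grid'")
  if (cfg$kind == "sweep-length") {
    if (is.null(cfg$L_grid)) stop("sweep-length needs an 'L_grid'")
    if (is.null(cfg$pause_density)) stop("sweep-length needs 'pause_density'")
  }
  if (cfg$kind == "steady-state" && is.null(cfg$n_steps))
    stop("steady-state needs 'n_steps'")
  if (cfg$kind == "fidelity-sim") {
    need("reference", c("length", "gc", "seed"))
    need("reads", c("n", "read_len", "seed"))
    need("error_model", c("e_tx", "e_rt", "e_seq"))
  }
  if (cfg$kind == "fidelity-run") {
    if (is.null(cfg$fastq) || is.null(cfg$reference))
      stop("fidelity-run needs 'fastq' and 'reference' paths")
  }
  if (is.null(cfg$seed)) stop("config needs a 'seed'")
  invisible(cfg)
}

#' Read and validate a YAML run configuration
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run a configured experiment and write its outputs
#'
#' Dispatches a validated configuration to the corresponding experiment,
#' writes the outputs as headed TSV (plus FASTA/FASTQ for read simulation)
#' into `outdir`, and drops the resolved configuration next to them, so a
#' run directory is self-describing and exactly reproducible from
#' `(config, seed)`.
#'
#' @param cfg Configuration list or YAML path.
#' @param outdir Output directory (created if needed).
#' @return List with `result` (the experiment's return value) and `files`
#'   (written paths), invisibly.
#' @export
run_experiment <- function(cfg, outdir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- NULL

  if (cfg$kind == "induction") {
    gene <- .gene_from_cfg(cfg$gene)
    params <- apply_scenario(.params_from_cfg(cfg$params),
                             .scenario_from_cfg(cfg$scenario))
    ind <- cfg$induction
    sig <- simulate_induction(gene, params,
                              n_runs = ind$n_runs, duration = ind$duration,
                              seed = cfg$seed,
                              record_interval = ind$record_interval)
    vel <- tryCatch(estimate_velocity(sig), error = function(e) NULL)
    files <- c(files, .write_tsv(as.data.frame(sig),
                                 file.path(outdir, "signals.tsv")))
    if (!is.null(vel))
      files <- c(files, .write_tsv(
        data.frame(velocity = vel$velocity, onset_early = vel$onset_early,
                   onset_late = vel$onset_late,
                   probe_distance = vel$probe_distance),
        file.path(outdir, "velocity.tsv")))
    out <- list(signals = sig, velocity = vel)
  } else if (cfg$kind == "sweep-alpha") {
    gene <- .gene_from_cfg(cfg$gene)
    tab <- sweep_alpha(gene, .params_from_cfg(cfg$params),
                       .scenario_from_cfg(cfg$scenario),
                       alpha_grid = as.numeric(cfg$alpha_grid),
                       seed = cfg$seed)
    files <- c(files, .write_tsv(tab, file.path(outdir, "sweep_alpha.tsv")))
    out <- tab
  } else if (cfg$kind == "sweep-length") {
    tab <- sweep_length(.params_from_cfg(cfg$params),
                        .scenario_from_cfg(cfg$scenario),
                        L_grid = as.numeric(cfg$L_grid),
                        pause_density = cfg$pause_density,
                        seed = cfg$seed)
    files <- c(files, .write_tsv(tab, file.path(outdir, "sweep_length.tsv")))
    out <- tab
  } else if (cfg$kind == "steady-state") {
    gene <- .gene_from_cfg(cfg$gene)
    params <- apply_scenario(.params_from_cfg(cfg$params),
                             .scenario_from_cfg(cfg$scenario))
    res <- steady_state_rate(gene, params, n_steps = cfg$n_steps,
                             seed = cfg$seed, queue_stats = TRUE)
    files <- c(files, .write_tsv(
      data.frame(rate = res$rate, mean_occupancy = res$mean_occupancy,
                 mean_velocity = res$mean_velocity,
                 n_completions = res$n_completions,
                 mean_queue_size = res$queue_stats$mean_queue_size,
                 max_queue_size = res$queue_stats$max_queue_size,
                 fraction_snapshots_with_queue =
                   res$queue_stats$fraction_snapshots_with_queue),
      file.path(outdir, "steady_state.tsv")))
    out <- res
  } else if (cfg$kind == "fidelity-sim") {
    ref <- generate_reference(cfg$reference$length, cfg$reference$gc,
                              cfg$reference$seed)
    model <- error_model(cfg$error_model$e_tx, cfg$error_model$e_rt,
                         cfg$error_model$e_seq,
                         low_q_rate = if (is.null(cfg$error_model$low_q_rate))
                           0.005 else cfg$error_model$low_q_rate)
    rs <- generate_reads(ref, n = cfg$reads$n, read_len = cfg$reads$read_len,
                         model = model, seed = cfg$reads$seed)
    files <- c(files,
               write_reference(ref, file.path(outdir, "reference.fasta")),
               write_fastq(rs$reads, file.path(outdir, "reads.fastq")),
               write_manifest(rs$manifest, file.path(outdir, "manifest.tsv")))
    out <- rs
  } else if (cfg$kind == "fidelity-run") {
    pq <- run_pipeline(cfg$fastq, cfg$reference)
    rep <- pq$report
    files <- c(files, .write_tsv(
      data.frame(total_aligned_bases = rep$total_aligned_bases,
                 total_mismatches = rep$total_mismatches,
                 per_base_rate = rep$per_base_rate,
                 per_read_mean = rep$per_read_mean,
                 reads_with_mismatch_fraction = rep$reads_with_mismatch_fraction,
                 n_aligned_reads = rep$n_aligned_reads),
      file.path(outdir, "mismatch_report.tsv")))
    files <- c(files, .write_tsv(
      data.frame(stage = names(pq$stage_counts),
                 reads = as.integer(pq$stage_counts)),
      file.path(outdir, "stage_counts.tsv")))
    out <- pq
  }

  cfgp <- file.path(outdir, "resolved_config.yaml")
  yaml::write_yaml(cfg, cfgp)
  files <- c(files, cfgp)
  invisible(list(result = out, files = files))
}
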