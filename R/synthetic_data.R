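#' Default per-base quality profile
#'
#' A phred-38 plateau with a mild 3' decay to 30 over the last 35 cycles,
#' emulating a well-behaved short-read run.
#'
#' @param read_len Profile length (nt).
#' @return Integer vector of phred scores.
#' @export
default_quality_profile <- function(read_len = 135L) {
  decay <- min(35L, read_len)
  c(rep(38L, read_len - decay),
    as.integer(round(seq(38, 30, length.out = decay))))
}

#' Define an error model for synthetic reads
#'
#' Three independent per-base substitution channels applied in biological
#' order -- transcription (`e_tx`), reverse transcription (`e_rt`),
#' sequencing (`e_seq`) -- each replacing a base by one of the three other
#' bases uniformly. No indels are modelled (the downstream pipeline is
#' ungapped). The combined per-base mismatch probability used as ground
#' truth is `1 - (1 - e_tx) * (1 - e_rt) * (1 - e_seq)`.
#'
#' @param e_tx,e_rt,e_seq Channel probabilities, each in `[0, 0.1]`.
#' @param quality_profile Per-cycle phred scores (length >= read length).
#' @param low_q_rate Rate at which bases receive a low quality score
#'   (phred 3--14), to exercise the quality filter.
#' @return Object of class `error_model`.
#' @export
error_model <- function(e_tx = 0, e_rt = 0, e_seq = 0,
                        quality_profile = default_quality_profile(),
                        low_q_rate = 0.005) {
  e <- c(e_tx, e_rt, e_seq)
  if (any(e < 0 | e > 0.1))
    stop("error probabilities must lie in [0, 0.1]")
  structure(list(e_tx = e_tx, e_rt = e_rt, e_seq = e_seq,
                 quality_profile = as.integer(quality_profile),
                 low_q_rate = low_q_rate),
            class = "error_model")
}

#' Combined per-base mismatch probability of an error model
#' @param model An `error_model`.
#' @return Probability that a read base differs from the reference.
#' @export
combined_error_rate <- function(model) {
  1 - (1 - model$e_tx) * (1 - model$e_rt) * (1 - model$e_seq)
}

#' Generate a random reference sequence
#'
#' @param length Sequence length (nt), at least 1000.
#' @param gc Expected GC fraction (the pneumococcal genome sits near 0.4).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return A `DNAString`.
#' @export
generate_reference <- function(length, gc = 0.4, seed = 1L) {
  if (length < 1000) stop("reference must be at least 1000 nt")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  set.seed(as.integer(seed))
  b <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  Biostrings::DNAString(paste(b, collapse = ""))
}

#' Write a reference sequence to FASTA
#' @param reference A `DNAString`.
#' @param path Output path.
#' @param name Sequence name.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path, name = "synthetic_reference") {
  ss <- Biostrings::DNAStringSet(reference)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

.BASES <- c("A", "C", "G", "T")

.apply_channel <- function(mat, mask) {
  idx <- which(mask)
  if (!length(idx)) return(mat)
  off <- sample.int(3L, length(idx), replace = TRUE)
  ci <- match(mat[idx], .BASES)
  mat[idx] <- .BASES[((ci - 1L + off) %% 4L) + 1L]
  mat
}

.mask_positions <- function(mask, n) {
  apply(mask, 1L, function(v) paste(which(v), collapse = ","))
}

#' Generate synthetic FASTQ reads with known ground truth
#'
#' Read origins are uniform over both strands of the reference. The three
#' error channels are applied sequentially in read coordinates; a manifest
#' records every read's true origin and the injected error positions per
#' channel, so downstream estimates can be checked against ground truth.
#'
#' Each channel's Bernoulli error mask is drawn from its own sub-seed
#' (`seed + 1..3`; substitution identities from `seed + 4`, qualities from
#' `seed + 5`). Two runs sharing a seed but differing in one channel's rate
#' therefore share all other channels' error positions exactly (common
#' random numbers), which makes paired comparisons sharp.
#'
#' @param reference A `DNAString` (or character / FASTA path).
#' @param n Number of reads (> 0).
#' @param read_len Read length (nt); default 135 (trimming 20 + 20 leaves a
#'   95-nt core).
#' @param model An [error_model()].
#' @param seed Integer base seed.
#' @return List with `reads` (a named `QualityScaledDNAStringSet`) and
#'   `manifest` (data frame: `id`, `start`, `strand`, per-channel error
#'   counts and comma-joined read-coordinate positions).
#' @export
generate_reads <- function(reference, n, read_len = 135L, model = error_model(),
                           seed = 1L) {
  if (n <= 0) stop("n must be positive")
  stopifnot(inherits(model, "error_model"))
  ref <- .as_dnastring(reference)
  L <- length(ref)
  if (read_len > L) stop("read_len exceeds the reference length")
  if (length(model$quality_profile) < read_len)
    stop("quality profile shorter than the read length")
  seed <- as.integer(seed)

  set.seed(seed)
  starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)

  refc <- as.character(ref)
  seqs <- substring(refc, starts, starts + read_len - 1L)
  minus <- strands == "-"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))

  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)

  masks <- list()
  rates <- c(tx = model$e_tx, rt = model$e_rt, seq = model$e_seq)
  for (k in seq_along(rates)) {
    set.seed(seed + k)
    masks[[k]] <- matrix(runif(n * read_len) < rates[k], nrow = n)
  }

  set.seed(seed + 4L)
  for (k in seq_along(masks)) mat <- .apply_channel(mat, masks[[k]])

  set.seed(seed + 5L)
  profile <- model$quality_profile[seq_len(read_len)]
  qmat <- matrix(rep(profile, each = n), nrow = n)
  low <- matrix(runif(n * read_len) < model$low_q_rate, nrow = n)
  if (any(low)) qmat[low] <- sample(3:14, sum(low), replace = TRUE)

  ids <- sprintf("read_%06d", seq_len(n))
  seq_out <- apply(mat, 1L, paste, collapse = "")
  qual_out <- apply(qmat, 1L, function(v) intToUtf8(v + 33L))
  dna <- Biostrings::DNAStringSet(seq_out)
  names(dna) <- ids
  reads <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(qual_out))

  manifest <- data.frame(
    id = ids, start = starts, strand = strands,
    n_tx = rowSums(masks[[1]]), n_rt = rowSums(masks[[2]]),
    n_seq = rowSums(masks[[3]]),
    pos_tx = .mask_positions(masks[[1]], n),
    pos_rt = .mask_positions(masks[[2]], n),
    pos_seq = .mask_positions(masks[[3]], n),
    stringsAsFactors = FALSE)

  list(reads = reads, manifest = manifest)
}

#' Write a read-set manifest as TSV
#' @param manifest Manifest data frame from [generate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fidelity presets: genotype x reverse transcriptase grid
#'
#' Error-model presets for the four simulated libraries (wild type /
#' Gre-less mutant, each reverse-transcribed with the high-fidelity
#' AccuScript or the lower-fidelity M-MLV enzyme). The channel rates are
#' package choices decomposed from published overall mismatch percentages
#' (~0.23/0.50% wild type and ~0.24/0.55% mutant for AccuScript/M-MLV);
#' the M-MLV:AccuScript ratio (~4.6x) sits inside the 3--6-fold fidelity
#' difference quoted by the enzyme supplier.
#'
#' @return Named list of four [error_model()] objects
#'   (`wt_accuscript`, `wt_mmlv`, `mut_accuscript`, `mut_mmlv`).
#' @export
fidelity_presets <- function() {
  e_seq <- 0.0010
  rt <- c(accuscript = 0.0008, mmlv = 0.0037)
  tx <- c(wt = 0.0005, mut = 0.0008)
  out <- list()
  for (g in names(tx))
    for (r in names(rt))
      out[[paste(g, r, sep = "_")]] <-
        error_model(e_tx = tx[[g]], e_rt = rt[[r]], e_seq = e_seq)
  out
}

#' Emit the default scenario suite as plain-text configs
#'
#' Writes eight YAML run configs with fixed seeds: the four kinetic
#' conditions (wild type plus the three Gre-loss hypotheses) as induction
#' experiments, and the four fidelity libraries (genotype x RT enzyme) as
#' read-simulation configs. All four fidelity configs share one read seed
#' so that pairwise comparisons are common-random-number coupled.
#' Regenerating the suite with the same arguments is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the written file paths, invisibly.
#' @export
make_scenario_suite <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  presets <- kinetic_presets()
  for (nm in names(presets)) {
    p <- presets[[nm]]$params
    s <- presets[[nm]]$scenario
    cfg <- list(
      kind = "induction",
      gene = list(L = 2700L, pause_density = 0.002, seed = 73L),
      params = list(alpha = p$alpha, epsilon = p$epsilon, f = p$f,
                    tau = p$tau, footprint = p$footprint, dt = p$dt),
      scenario = list(name = s$name, factor = s$factor),
      induction = list(n_runs = 1000L, duration = 150, record_interval = 0.5),
      seed = 1L)
    fp <- file.path(dir, paste0("kinetic_", nm, ".yaml"))
    yaml::write_yaml(cfg, fp)
    paths <- c(paths, fp)
  }
  fids <- fidelity_presets()
  for (nm in names(fids)) {
    m <- fids[[nm]]
    cfg <- list(
      kind = "fidelity-sim",
      reference = list(length = 10000L, gc = 0.4, seed = 101L),
      reads = list(n = 800L, read_len = 135L, seed = 211L),
      error_model = list(e_tx = m$e_tx, e_rt = m$e_rt, e_seq = m$e_seq,
                         low_q_rate = m$low_q_rate),
      label = nm,
      seed = 211L)
    fp <- file.path(dir, paste0("fidelity_", nm, ".yaml"))
    yaml::write_yaml(cfg, fp)
    paths <- c(paths, fp)
  }
  invisible(paths)
}
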