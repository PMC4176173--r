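#' Read a FASTQ file into a quality-scaled read set
#'
#' Reads are held as a `QualityScaledDNAStringSet` (Sanger/phred+33
#' qualities) throughout the pipeline.
#'
#' @param path FASTQ file path.
#' @return A `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  # the reader notes that it drops per-read metadata columns; the pipeline
  # never uses them, so silence that specific warning
  reads <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  methods::slot(reads, "elementMetadata") <- NULL
  reads
}

#' Write a read set to FASTQ (phred+33)
#' @param reads A `QualityScaledDNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(reads, path),
    warning = function(w) {
      # dropping the (unused) metadata columns is expected
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

#' Read a FASTA reference (first sequence)
#' @param path FASTA file path.
#' @return A `DNAString`.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty reference FASTA")
  ss[[1L]]
}

#' Per-base integer phred scores of a read set
#' @param reads A `QualityScaledDNAStringSet`.
#' @return List of integer vectors, one per read.
#' @export
quality_ints <- function(reads) {
  lapply(as.character(Biostrings::quality(reads)),
         function(s) utf8ToInt(s) - 33L)
}

.as_dnastring <- function(x) {
  if (methods::is(x, "DNAString")) x
  else if (methods::is(x, "DNAStringSet")) x[[1L]]
  else if (is.character(x) && length(x) == 1L && !grepl("[^ACGTNacgtn]", x))
    Biostrings::DNAString(toupper(x))
  else if (is.character(x) && length(x) == 1L) read_reference(x)
  else stop("cannot interpret the reference")
}

#' Reject reads containing long homopolymer runs
#'
#' Drops every read whose raw (untrimmed) sequence contains a run of
#' `max_run + 1` or more identical nucleotides; with the default
#' `max_run = 4`, runs of five or more (e.g. `TTTTT`) are rejected, runs of
#' four are kept. Long homopolymers inflate apparent mismatch and indel
#' rates on short-read platforms, so they are removed before anything else.
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param max_run Longest tolerated run (nt).
#' @return The surviving reads.
#' @export
filter_homopolymer <- function(reads, max_run = 4L) {
  pat <- sprintf("([ACGTN])\\1{%d,}", as.integer(max_run))
  reads[!grepl(pat, as.character(reads))]
}

#' Trim reads to their high-confidence core
#'
#' Removes the first `head` and last `tail` bases of every read (sequence
#' and qualities alike); reads too short to trim are dropped. With the
#' defaults, 135-nt reads become 95-nt reads.
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param head,tail Bases removed from each end.
#' @param expect_len If non-`NULL`, warn when any trimmed read deviates
#'   from this length.
#' @return The trimmed reads (short reads removed, with a warning giving
#'   the count).
#' @export
trim_reads <- function(reads, head = 20L, tail = 20L, expect_len = 95L) {
  w <- Biostrings::width(reads)
  short <- w < head + tail + 1L
  if (any(short)) {
    warning(sum(short), " read(s) shorter than head + tail + 1 were dropped")
    reads <- reads[!short]
    w <- w[!short]
  }
  if (length(reads) == 0L) return(reads)
  out <- Biostrings::subseq(reads, start = head + 1L, end = w - tail)
  if (!is.null(expect_len)) {
    off <- Biostrings::width(out) != expect_len
    if (any(off))
      warning(sum(off), " trimmed read(s) deviate from the expected ",
              expect_len, " nt")
  }
  out
}

#' Quality-filter reads on mean and minimum phred score
#'
#' Keeps a read only if its mean phred score is at least `min_mean_q` and
#' no single base falls below `min_q`.
#'
#' @param reads A `QualityScaledDNAStringSet` (normally trimmed).
#' @param min_mean_q Minimum mean phred score.
#' @param min_q Minimum per-base phred score.
#' @return The surviving reads.
#' @export
quality_filter <- function(reads, min_mean_q = 25, min_q = 15) {
  if (length(reads) == 0L) return(reads)
  q <- quality_ints(reads)
  keep <- vapply(q, function(v) mean(v) >= min_mean_q && min(v) >= min_q,
                 logical(1))
  reads[keep]
}

#' Map reads to a reference by exhaustive ungapped alignment
#'
#' Every read is slid over both strands of the reference; a read is
#' reported only when it has exactly one best-scoring (fewest mismatches)
#' ungapped placement with at most `max_mismatches` mismatches. Ties and
#' reads exceeding the mismatch budget are counted as unmapped. Exhaustive
#' search guarantees correctness on the small references this pipeline
#' targets (up to ~100 kb).
#'
#' @param reads A `QualityScaledDNAStringSet` (or `DNAStringSet`).
#' @param reference A `DNAString`, single-sequence `DNAStringSet`, FASTA
#'   path, or DNA character string.
#' @param max_mismatches Maximum mismatches for a reportable placement.
#' @return Object of class `read_alignments`: a data frame with `read_id`,
#'   `ref_start`, `strand`, `n_mismatch` and `seq_ref_oriented` (the read
#'   in reference orientation), with attributes `n_input`, `n_mapped`,
#'   `n_unmapped` and `reference`.
#' @export
map_reads <- function(reads, reference, max_mismatches = 6L) {
  ref <- .as_dnastring(reference)
  if (length(ref) == 0L) stop("empty reference")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
  seqs <- as.character(reads)
  if (any(nchar(seqs) > length(ref)))
    stop("reference shorter than the reads")

  rows <- vector("list", length(seqs))
  n_mapped <- 0L
  for (i in seq_along(seqs)) {
    fwd <- Biostrings::DNAString(seqs[i])
    rev <- Biostrings::reverseComplement(fwd)
    hit_f <- Biostrings::matchPattern(fwd, ref, max.mismatch = max_mismatches)
    hit_r <- Biostrings::matchPattern(rev, ref, max.mismatch = max_mismatches)
    st_f <- Biostrings::start(hit_f)
    st_r <- Biostrings::start(hit_r)
    mm <- c(
      if (length(st_f)) Biostrings::neditStartingAt(fwd, ref, starting.at = st_f,
                                                    fixed = TRUE) else integer(0),
      if (length(st_r)) Biostrings::neditStartingAt(rev, ref, starting.at = st_r,
                                                    fixed = TRUE) else integer(0))
    if (!length(mm)) next
    best <- min(mm)
    if (sum(mm == best) != 1L) next  # ambiguous placement: discard
    k <- which.min(mm)
    minus <- k > length(st_f)
    rows[[i]] <- data.frame(
      read_id = ids[i],
      ref_start = if (minus) st_r[k - length(st_f)] else st_f[k],
      strand = if (minus) "-" else "+",
      n_mismatch = best,
      seq_ref_oriented = as.character(if (minus) rev else fwd),
      stringsAsFactors = FALSE)
    n_mapped <- n_mapped + 1L
  }
  out <- if (n_mapped) do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
         else data.frame(read_id = character(0), ref_start = integer(0),
                         strand = character(0), n_mismatch = integer(0),
                         seq_ref_oriented = character(0))
  attr(out, "n_input") <- length(seqs)
  attr(out, "n_mapped") <- n_mapped
  attr(out, "n_unmapped") <- length(seqs) - n_mapped
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Tally mismatches of aligned reads against the reference
#'
#' Compares every aligned base to the reference, position by position and
#' strand-aware. `N` bases in a read are excluded from both the numerator
#' and the denominator.
#'
#' @param alignments A `read_alignments` object from [map_reads()].
#' @param reference The same reference given to [map_reads()].
#' @param stage_counts Optional named integer vector of read counts along
#'   the filter cascade, carried into the report.
#' @return Object of class `mismatch_report`: `total_aligned_bases`,
#'   `total_mismatches`, `per_base_rate` (percent), `per_read_mean`
#'   (mismatches per aligned read), `reads_with_mismatch_fraction`
#'   (percent), `n_aligned_reads` and `stage_counts`.
#' @export
tally_mismatches <- function(alignments, reference, stage_counts = NULL) {
  ref_chars <- strsplit(as.character(.as_dnastring(reference)), "", fixed = TRUE)[[1L]]
  n_reads <- nrow(alignments)
  total_bases <- 0L; total_mm <- 0L; reads_with_mm <- 0L
  if (n_reads > 0L) {
    for (i in seq_len(n_reads)) {
      rc <- strsplit(alignments$seq_ref_oriented[i], "", fixed = TRUE)[[1L]]
      idx <- seq.int(alignments$ref_start[i], length.out = length(rc))
      ok <- rc != "N"
      mm <- sum(rc[ok] != ref_chars[idx][ok])
      total_bases <- total_bases + sum(ok)
      total_mm <- total_mm + mm
      if (mm > 0L) reads_with_mm <- reads_with_mm + 1L
    }
  }
  structure(
    list(total_aligned_bases = total_bases,
         total_mismatches = total_mm,
         per_base_rate = if (total_bases > 0) 100 * total_mm / total_bases
                         else NA_real_,
         per_read_mean = if (n_reads > 0) total_mm / n_reads else NA_real_,
         reads_with_mismatch_fraction = if (n_reads > 0)
           100 * reads_with_mm / n_reads else NA_real_,
         n_aligned_reads = n_reads,
         zero_denominator = total_bases == 0L,
         stage_counts = stage_counts),
    class = "mismatch_report")
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf(
    "<mismatch_report> %.4g%% per base (%d mismatches / %d aligned bases); %.3g per read; %.3g%% of %d reads carry a mismatch\n",
    x$per_base_rate, x$total_mismatches, x$total_aligned_bases,
    x$per_read_mean, x$reads_with_mismatch_fraction, x$n_aligned_reads))
  if (!is.null(x$stage_counts)) {
    cat("  cascade:",
        paste(names(x$stage_counts), x$stage_counts, sep = "=",
              collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Run the full mismatch-rate pipeline
#'
#' Applies, in order: the homopolymer filter (on raw reads), trimming,
#' the quality filter, unique-best ungapped mapping, and the mismatch
#' tally. Stage read counts are logged to stderr and carried in the
#' report.
#'
#' @param reads A `QualityScaledDNAStringSet` or FASTQ path.
#' @param reference A `DNAString`, FASTA path, or DNA character string.
#' @param max_run,trim_head,trim_tail,expect_len,min_mean_q,min_q,max_mismatches
#'   Stage parameters; see the stage functions.
#' @param out_fastq Optional path: write the filtered (pre-mapping) reads.
#' @param quiet Suppress the per-stage log lines.
#' @return List with `report` (a `mismatch_report`), `alignments`,
#'   `reads` (the filtered read set) and `stage_counts`.
#' @export
run_pipeline <- function(reads, reference, max_run = 4L,
                         trim_head = 20L, trim_tail = 20L, expect_len = 95L,
                         min_mean_q = 25, min_q = 15, max_mismatches = 6L,
                         out_fastq = NULL, quiet = FALSE) {
  if (is.character(reads)) reads <- read_fastq(reads)
  n0 <- length(reads)
  r1 <- filter_homopolymer(reads, max_run)
  r2 <- suppressWarnings(trim_reads(r1, trim_head, trim_tail, expect_len))
  r3 <- quality_filter(r2, min_mean_q, min_q)
  aln <- map_reads(r3, reference, max_mismatches)
  counts <- c(input = n0, homopolymer = length(r1), trimmed = length(r2),
              quality = length(r3), mapped = attr(aln, "n_mapped"))
  if (!quiet)
    message("pipeline stages [reads]: ",
            paste(names(counts), counts, sep = "=", collapse = " -> "))
  report <- tally_mismatches(aln, reference, stage_counts = counts)
  if (report$zero_denominator && !quiet)
    message("no aligned bases survive the cascade; rates are undefined")
  if (!is.null(out_fastq)) write_fastq(r3, out_fastq)
  list(report = report, alignments = aln, reads = r3, stage_counts = counts)
}
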