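mk_reads <- function(seqs, q = 38L) {
  quals <- vapply(nchar(seqs),
                  function(n) intToUtf8(rep(q + 33L, n)), character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- sprintf("r%03d", seq_along(seqs))
  Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(quals))
}

no_run_seq <- function(n) {
  substr(strrep("ACGT", ceiling(n / 4) + 1), 1, n)
}

test_that("homopolymer filter rejects runs of five or more, keeps four", {
  core <- no_run_seq(60)
  reads <- mk_reads(c(
    paste0(core, "TTTTT", no_run_seq(70)),   # run of 5 -> rejected
    paste0(core, "AAAA", "CGT", no_run_seq(68)), # run of 4 -> kept
    no_run_seq(135),                          # no runs -> kept
    paste0(core, "GGGGGGG", no_run_seq(68)))) # run of 7 -> rejected
  kept <- filter_homopolymer(reads)
  expect_identical(names(kept), c("r002", "r003"))
  # the threshold is configurable: tolerating runs of six readmits r001
  expect_length(filter_homopolymer(reads, max_run = 6), 3L)
})

test_that("trimming removes 20 + 20 bases from sequence and qualities", {
  reads <- mk_reads(no_run_seq(135))
  tr <- trim_reads(reads)
  expect_identical(Biostrings::width(tr), 95L)
  expect_identical(nchar(as.character(Biostrings::quality(tr))), 95L)
  expect_identical(as.character(tr)[[1]],
                   substr(no_run_seq(135), 21, 115))

  expect_warning(tr1 <- trim_reads(mk_reads(no_run_seq(41))), "deviate")
  expect_identical(Biostrings::width(tr1), 1L)
  expect_warning(tr0 <- trim_reads(mk_reads(no_run_seq(40))), "dropped")
  expect_length(tr0, 0L)
})

test_that("quality filter applies the mean-25 and min-15 rules", {
  dna <- Biostrings::DNAStringSet(rep(no_run_seq(10), 3))
  names(dna) <- c("all25", "one14", "mean24")
  q <- c(intToUtf8(rep(25L + 33L, 10)),
         intToUtf8(c(rep(40L + 33L, 9), 14L + 33L)),
         intToUtf8(rep(24L + 33L, 10)))
  reads <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(q))
  expect_identical(names(quality_filter(reads)), "all25")
})

test_that("the mapper reports unique best ungapped placements only", {
  ref <- generate_reference(2000, 0.5, seed = 50)
  refc <- as.character(ref)
  clean <- substr(refc, 301, 395)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(clean)))
  mutated <- clean
  substr(mutated, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(clean, 10, 10))[1]
  seven <- clean
  for (i in seq(5, 65, by = 10))
    substr(seven, i, i) <- setdiff(c("A", "C", "G", "T"),
                                   substr(clean, i, i))[1]
  aln <- map_reads(mk_reads(c(clean, rc, mutated, seven)), ref)
  expect_identical(attr(aln, "n_mapped"), 3L)
  expect_identical(aln$strand, c("+", "-", "+"))
  expect_identical(aln$ref_start, c(301L, 301L, 301L))
  expect_identical(aln$n_mismatch, c(0L, 0L, 1L))

  # duplicated locus: a read matching both copies is ambiguous -> unmapped
  dup <- paste0(substr(refc, 1, 500), substr(refc, 201, 500))
  aln2 <- map_reads(mk_reads(substr(refc, 301, 395)), dup)
  expect_identical(attr(aln2, "n_mapped"), 0L)
})

test_that("mismatch tallying does the arithmetic and excludes N bases", {
  ref <- generate_reference(2000, 0.5, seed = 51)
  refc <- as.character(ref)
  reads <- vapply(seq(101, 1001, by = 100),
                  function(s) substr(refc, s, s + 94), character(1))
  substr(reads[1], 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                      substr(reads[1], 50, 50))[1]
  rep0 <- tally_mismatches(map_reads(mk_reads(reads), ref), ref)
  expect_identical(rep0$total_aligned_bases, 950L)
  expect_identical(rep0$total_mismatches, 1L)
  expect_equal(rep0$per_read_mean, 0.1)
  expect_equal(rep0$per_base_rate, 100 / 950)
  expect_equal(rep0$reads_with_mismatch_fraction, 10)

  withN <- reads[2]
  substr(withN, 30, 30) <- "N"
  repN <- tally_mismatches(map_reads(mk_reads(withN), ref), ref)
  expect_identical(repN$total_aligned_bases, 94L)
  expect_identical(repN$total_mismatches, 0L)
})

test_that("the cascade is order-faithful: raw homopolymers reject a read
           even when trimming would have removed them", {
  lead <- "GTTTTTGACGTACGTACGTA"          # homopolymer inside the first 20 nt
  stopifnot(nchar(lead) == 20)
  read <- paste0(lead, no_run_seq(115))
  counts <- run_pipeline(mk_reads(read), generate_reference(1500, 0.5, 1),
                         quiet = TRUE)$stage_counts
  expect_identical(unname(counts["homopolymer"]), 0L)
  expect_true(all(diff(unname(counts)) <= 0))
})

test_that("error-free libraries give a zero mismatch rate end to end", {
  ref <- generate_reference(5000, 0.4, seed = 60)
  rs <- generate_reads(ref, 150, model = error_model(0, 0, 0, low_q_rate = 0),
                       seed = 61)
  out <- run_pipeline(rs$reads, ref, quiet = TRUE)
  expect_gt(out$report$n_aligned_reads, 50)
  expect_identical(out$report$total_mismatches, 0L)
  expect_equal(out$report$per_base_rate, 0)
  expect_true(all(diff(unname(out$stage_counts)) <= 0))
})

test_that("per-base rate estimates are unbiased across seeds", {
  ref <- generate_reference(8000, 0.4, seed = 70)
  model <- error_model(e_tx = 0.001, e_rt = 0.002, e_seq = 0.003)
  p <- combined_error_rate(model)
  zs <- vapply(71:75, function(sd) {
    rs <- generate_reads(ref, 700, model = model, seed = sd)
    out <- run_pipeline(rs$reads, ref, quiet = TRUE)
    n <- out$report$total_aligned_bases
    (out$report$total_mismatches - n * p) / sqrt(n * p * (1 - p))
  }, numeric(1))
  # mean standardized bias within twice its own standard error
  expect_lt(abs(mean(zs)), 2 / sqrt(length(zs)))
})

test_that("mapped placements agree with the generator's manifest", {
  ref <- generate_reference(8000, 0.4, seed = 70)
  model <- error_model(e_tx = 0.001, e_rt = 0.002, e_seq = 0.003)
  rs <- generate_reads(ref, 700, model = model, seed = 71)
  out <- run_pipeline(rs$reads, ref, quiet = TRUE)
  mf <- rs$manifest[match(out$alignments$read_id, rs$manifest$id), ]
  expect_gte(mean(out$alignments$ref_start == mf$start + 20L &
                  out$alignments$strand == mf$strand), 0.999)
})

test_that("each error channel raises the mismatch rate when raised alone", {
  ref <- generate_reference(6000, 0.4, seed = 80)
  base <- list(e_tx = 0.002, e_rt = 0.002, e_seq = 0.002)
  rate_for <- function(m) {
    rs <- generate_reads(ref, 500, model = do.call(error_model, m), seed = 81)
    run_pipeline(rs$reads, ref, quiet = TRUE)$report$per_base_rate
  }
  r0 <- rate_for(base)
  for (ch in names(base)) {
    up <- base
    up[[ch]] <- 0.006
    expect_gt(rate_for(up), r0)
  }
})
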