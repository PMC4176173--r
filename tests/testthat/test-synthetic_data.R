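test_that("reference generation honours length, composition and seed", {
  ref <- generate_reference(10000, 0.5, seed = 7)
  expect_identical(length(ref), 10000L)
  expect_identical(as.character(generate_reference(10000, 0.5, seed = 7)),
                   as.character(ref))
  gc_only <- generate_reference(1000, 1.0, seed = 7)
  expect_false(grepl("[AT]", as.character(gc_only)))
  gc <- Biostrings::letterFrequency(generate_reference(50000, 0.4, 8),
                                    "GC", as.prob = TRUE)
  expect_equal(unname(gc), 0.4, tolerance = 0.02)
  expect_error(generate_reference(500, 0.5, 1), "at least 1000")
})

test_that("zero-error reads are exact substrings at their manifest origins", {
  ref <- generate_reference(4000, 0.4, seed = 9)
  refc <- as.character(ref)
  rs <- generate_reads(ref, 80, model = error_model(0, 0, 0), seed = 10)
  seqs <- as.character(rs$reads)
  for (i in seq_len(80)) {
    src <- substr(refc, rs$manifest$start[i], rs$manifest$start[i] + 134L)
    if (rs$manifest$strand[i] == "-")
      src <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(src)))
    expect_identical(unname(seqs[i]), src)
  }
  expect_true(all(rs$manifest$n_tx + rs$manifest$n_rt + rs$manifest$n_seq == 0))
})

test_that("injected error counts agree with their binomial law", {
  ref <- generate_reference(5000, 0.4, seed = 12)
  rs <- generate_reads(ref, 3000, model = error_model(e_seq = 0.01),
                       seed = 13)
  n_bases <- 3000 * 135
  total <- sum(rs$manifest$n_seq)
  ci <- qbinom(c(0.0025, 0.9975), n_bases, 0.01)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
  # error positions recorded in the manifest match the sequence differences
  i <- which(rs$manifest$n_seq > 0)[1]
  pos <- as.integer(strsplit(rs$manifest$pos_seq[i], ",")[[1]])
  src <- substr(as.character(ref), rs$manifest$start[i],
                rs$manifest$start[i] + 134L)
  if (rs$manifest$strand[i] == "-")
    src <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(src)))
  read_chars <- strsplit(as.character(rs$reads)[[i]], "")[[1]]
  src_chars <- strsplit(src, "")[[1]]
  expect_true(all(read_chars[pos] != src_chars[pos]))
})

test_that("paired seeds couple the shared channels exactly", {
  ref <- generate_reference(3000, 0.4, seed = 14)
  lo <- generate_reads(ref, 200, model = error_model(e_rt = 0.001,
                                                     e_seq = 0.002), seed = 15)
  hi <- generate_reads(ref, 200, model = error_model(e_rt = 0.004,
                                                     e_seq = 0.002), seed = 15)
  expect_identical(lo$manifest$pos_seq, hi$manifest$pos_seq)
  expect_identical(lo$manifest$start, hi$manifest$start)
  # the low-rate rt mask is a subset of the high-rate mask
  expect_true(all(lo$manifest$n_rt <= hi$manifest$n_rt))
  expect_gt(sum(hi$manifest$n_rt), sum(lo$manifest$n_rt))
})

test_that("qualities follow the profile with a low-quality tail", {
  ref <- generate_reference(3000, 0.4, seed = 16)
  rs <- generate_reads(ref, 400, model = error_model(low_q_rate = 0.01),
                       seed = 17)
  q <- quality_ints(rs$reads)
  expect_true(all(lengths(q) == 135L))
  flat <- unlist(q)
  expect_true(any(flat < 15))            # tail injections present
  expect_equal(mean(flat >= 30), 1 - 0.01, tolerance = 0.005)
})

test_that("the scenario suite is complete, valid and byte-stable", {
  d1 <- file.path(tempdir(), "suite1")
  d2 <- file.path(tempdir(), "suite2")
  p1 <- make_scenario_suite(d1)
  p2 <- make_scenario_suite(d2)
  expect_length(p1, 8L)
  expect_identical(sum(grepl("kinetic_", basename(p1))), 4L)
  expect_identical(sum(grepl("fidelity_", basename(p1))), 4L)
  for (fp in p1) expect_silent(validate_run_config(yaml::read_yaml(fp)))
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  # the four fidelity configs cover the genotype x enzyme grid
  fids <- grep("fidelity_", p1, value = TRUE)
  labs <- vapply(fids, function(fp) yaml::read_yaml(fp)$label, character(1))
  expect_setequal(unname(labs), c("wt_accuscript", "wt_mmlv",
                                  "mut_accuscript", "mut_mmlv"))
})
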