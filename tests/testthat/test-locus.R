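test_that("digestion produces tiling fragments at motif cut sites", {
  # no cut site: whole sequence is one fragment
  fr <- digest_sequence("ACGTACGT")
  expect_equal(nrow(fr), 1L)
  expect_equal(c(fr$start, fr$end), c(0L, 8L))

  # two interior HindIII sites, cut-at-motif-start convention
  fr <- digest_sequence("CCAAGCTTGGAAGCTTCC")
  expect_equal(fr$start, c(0L, 2L, 10L))
  expect_equal(fr$end, c(2L, 10L, 18L))
  expect_equal(fr$fragment_id, 1:3)

  # configurable cut offset shifts boundaries within the motif
  fr1 <- digest_sequence("CCAAGCTTGGAAGCTTCC", cut_offset = 1L)
  expect_equal(fr1$start, c(0L, 3L, 11L))

  # lower-case input is normalised
  expect_equal(digest_sequence("ccaagcttgg")$start, c(0L, 2L))
})

test_that("digestion rejects invalid input and never matches N", {
  expect_error(digest_sequence(""), "non-empty")
  expect_error(digest_sequence("ACGTXX"), "A/C/G/T/N")
  expect_error(digest_sequence("ACGTACGT", motif = "AANCTT"), "only A/C/G/T")
  expect_error(digest_sequence("ACGTACGT", motif = "ACG"), ">= 4")
  # N in the sequence breaks a would-be site
  expect_equal(nrow(digest_sequence("CCAAGCTNGGACGT")), 1L)
})

test_that("digestion agrees with a naive substring-scan oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(50:10000, 1)
    s <- random_dna(n)
    # inject a few sites so most sequences are actually cut
    for (p in sample(seq_len(max(n - 10, 1)), min(3, n %/% 100))) {
      substr(s, p, p + 5) <- "AAGCTT"
    }
    got <- digest_sequence(s)
    want <- naive_fragments(s, "AAGCTT")
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # tiling: lengths sum to sequence length, no gaps or overlaps
    expect_equal(sum(got$length), nchar(s))
    if (nrow(got) > 1)
      expect_equal(got$start[-1], got$end[-nrow(got)])
  }
})

test_that("TSS distances are signed kb from fragment midpoints", {
  fr <- data.frame(fragment_id = 1:2, chrom = "locus",
                   start = c(0L, 2000L), end = c(2000L, 4000L),
                   length = 2000L)
  plus <- assign_tss_distances(fr, tss = 2000, gene_strand = "+")
  expect_equal(plus$tss_distance_kb, c(-1, 1))
  minus <- assign_tss_distances(fr, tss = 2000, gene_strand = "-")
  expect_equal(minus$tss_distance_kb, c(1, -1))
  expect_error(assign_tss_distances(fr, tss = 5000), "outside the locus")
})

test_that("fragment lookup respects half-open boundaries", {
  lm <- locus_model(sequence = "CCAAGCTTGGAAGCTTCC", tss = 5)
  fr <- lm$fragments
  expect_equal(locate_fragment(lm, fr$start[2]), 2)
  expect_equal(locate_fragment(lm, fr$end[2]), 3)
  expect_equal(locate_fragment(lm, 0), 1)
  expect_error(locate_fragment(lm, 18), "outside")
  expect_equal(lm$bait_fragment_id, 2)  # fragment [2,10) contains tss = 5
})

test_that("fragments round-trip through BED and FASTA through disk", {
  sc <- preset_scenario("pc3m", seed = 7)
  locus <- threeCquant:::scenario_locus(sc)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_fragments_bed(locus$fragments, bed, strand = "+")
  back <- read_fragments_bed(bed)
  expect_equal(back$start, locus$fragments$start)
  expect_equal(back$end, locus$fragments$end)
  expect_equal(back$name, as.character(locus$fragments$fragment_id))

  fa <- withr::local_tempfile(fileext = ".fa")
  s <- random_dna(500)
  write_locus_fasta(s, fa)
  expect_equal(read_locus_fasta(fa), s)
  # multi-record FASTA is rejected by name
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa)
  expect_error(read_locus_fasta(fa), "expected exactly 1 FASTA record")
})
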