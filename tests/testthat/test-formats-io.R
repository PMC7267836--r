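# FASTA/FASTQ parsing, configuration, and pair merging.

test_that("FASTA reading concatenates lines, validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC", "GT", ">b", "TT"), f)
  x <- read_fasta(f)
  expect_equal(x$id, c("a", "b"))
  expect_equal(x$seq, c("ACGT", "TT"))

  writeLines(c(">a", "acgt"), f)
  expect_equal(read_fasta(f)$seq, "ACGT")

  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate id")
  writeLines(c(">a", ">b", "GG"), f)
  expect_error(read_fasta(f), "empty sequence")
  writeLines(c("ACGT"), f)
  expect_error(read_fasta(f), "line 1")

  y <- tibble::tibble(id = c("r1", "r2"),
                      seq = c(rand_seq(130, 1), rand_seq(77, 2)))
  write_fasta(y, f)
  expect_equal(read_fasta(f), y)
  write_fasta(y, f, width = 60)          # wrapped output reads back equal
  expect_equal(read_fasta(f), y)
})

test_that("paired FASTQ files are matched by order and validated", {
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1/1", "ACGT", "+", "IIII"), f1)
  writeLines(c("@r1/2", "TTGG", "+", "IIII"), f2)
  p <- read_fastq_pairs(f1, f2, "S1")
  expect_equal(nrow(p), 1)
  expect_equal(p$id, "r1")
  expect_equal(p$sample, "S1")

  writeLines(character(0), f1); writeLines(character(0), f2)
  expect_equal(nrow(read_fastq_pairs(f1, f2, "S1")), 0)

  writeLines(rep(c("@r", "ACGT", "+", "IIII"), 3), f1)
  writeLines(rep(c("@r", "ACGT", "+", "IIII"), 2), f2)
  expect_error(read_fastq_pairs(f1, f2, "S1"), "record count")

  writeLines(c("@r1/1", "ACGT", "+", "III"), f1)
  writeLines(c("@r1/2", "TTGG", "+", "IIII"), f2)
  expect_error(read_fastq_pairs(f1, f2, "S1"), "length mismatch")

  # write/read round trip
  pp <- full_overlap_pairs(c(rand_seq(40, 5), rand_seq(40, 6)))
  write_fastq_pairs(pp, f1, f2)
  back <- read_fastq_pairs(f1, f2, "S1")
  expect_equal(back$seq1, pp$seq1)
  expect_equal(back$seq2, pp$seq2)
})

test_that("pair merging finds the best overlap and resolves it by quality", {
  # 5-base exact overlap: ACGTACGT + revcomp-of(TACGTGGG) -> 11 bases
  p <- tibble::tibble(id = "r1", seq1 = "ACGTACGT", qual1 = strrep("?", 8),
                      seq2 = revcomp("TACGTGGG"), qual2 = strrep("?", 8),
                      sample = "S1")
  m <- merge_pairs(p, min_overlap = 5, max_mismatch_rate = 0.05)
  expect_true(m$merged)
  expect_equal(nchar(m$mseq), 11)
  expect_equal(m$mseq, "ACGTACGTGGG")

  # full containment: seq2 = revcomp(seq1) merges to seq1 itself
  s <- rand_seq(60, 7)
  m2 <- merge_pairs(full_overlap_pair(s), min_overlap = 20)
  expect_true(m2$merged)
  expect_equal(m2$mseq, s)

  # non-overlapping random pair stays unmerged
  p3 <- tibble::tibble(id = "r3", seq1 = rand_seq(60, 8),
                       qual1 = strrep("?", 60), seq2 = rand_seq(60, 9),
                       qual2 = strrep("?", 60), sample = "S1")
  m3 <- merge_pairs(p3)
  expect_false(m3$merged)

  # overlap disagreement resolved by the higher quality score
  s1 <- paste0(rand_seq(30, 10), "ACGTACGTACGTACGTACGT")
  ov <- "ACGTACGTACGTACGTACGT"
  ov_mut <- paste0("T", substr(ov, 2, 20))   # mate 2 disagrees at base 1
  p4 <- tibble::tibble(id = "r4", seq1 = s1, qual1 = strrep("5", 50),
                       seq2 = revcomp(ov_mut), qual2 = strrep("I", 20),
                       sample = "S1")
  m4 <- merge_pairs(p4, min_overlap = 15, max_mismatch_rate = 0.1)
  expect_true(m4$merged)
  expect_equal(substr(m4$mseq, 31, 31), "T")  # higher-quality base wins

  # length bounds hold on random merging pairs
  withr::with_seed(11, {
    for (i in 1:20) {
      core <- rand_seq(80)
      s1 <- paste0(rand_seq(30), core)
      s2 <- revcomp(paste0(core, rand_seq(25)))
      pi <- tibble::tibble(id = "x", seq1 = s1, qual1 = strrep("?", 110),
                           seq2 = s2, qual2 = strrep("?", 105),
                           sample = "S1")
      mi <- merge_pairs(pi)
      if (isTRUE(mi$merged)) {
        expect_lte(nchar(mi$mseq), nchar(s1) + nchar(s2))
        expect_gte(nchar(mi$mseq), max(nchar(s1), nchar(s2)))
      }
    }
  })
})

test_that("configuration defaults match the documented operating point", {
  cfg <- default_config()
  expect_equal(cfg$sampling_num, 1e5)
  expect_equal(cfg$max_iterations, 11)
  expect_equal(cfg$novel_fraction_threshold, 0.01)
  expect_equal(cfg$derep_min_identity, 0.99)
  expect_equal(cfg$derep_max_edits, 5)
  expect_equal(cfg$map_minid, 0.96)
  expect_equal(cfg$map_idfilter, 0.98)
  expect_equal(cfg$map_minhits, 2)
  expect_equal(cfg$map_maxindel, 1)
  expect_equal(cfg$filter_min_coverage, 2.0)
  expect_equal(cfg$filter_min_covered_fraction, 0.80)
  expect_equal(cfg$base_seed, 1)
})

test_that("configuration files override defaults and are validated", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(character(0), f)
  cfg <- load_config(f)                   # empty file -> all defaults
  expect_equal(cfg$sampling_num, 1e5)
  expect_equal(cfg$max_iterations, 11)

  writeLines(c("# comment", "SAMPLING_NUM=1000000"), f)
  cfg <- load_config(f)
  expect_equal(cfg$sampling_num, 1e6)
  expect_equal(cfg$map_minid, 0.96)       # rest untouched

  writeLines("MAP_MINID=1.5", f)
  expect_error(load_config(f), "MAP_MINID")

  writeLines("NOT_A_KEY=3", f)
  expect_warning(load_config(f), "unknown configuration key")

  writeLines(c("SAMPLE=S1:a_1.fq:a_2.fq", "REFERENCE_FASTA=ref.fa"), f)
  cfg <- load_config(f)
  expect_equal(cfg$samples$S1, c("a_1.fq", "a_2.fq"))
  expect_equal(cfg$reference_fasta, "ref.fa")

  expect_error(default_config(map_minhits = 0), "map_minhits")
  expect_error(default_config(em_epsilon = 0.8), "em_epsilon")
})
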