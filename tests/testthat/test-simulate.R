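# Synthetic community generator: reference pools, communities, reads,
# scenarios.

test_that("reference pools share conserved blocks and diverge as expected", {
  # divergence 0 -> all species identical
  p0 <- make_reference_pool(4, length = 500, n_conserved_blocks = 4,
                            divergence = 0, seed = 1)
  expect_equal(length(unique(p0$seq)), 1)

  # conserved blocks are bit-identical across species
  p <- make_reference_pool(5, length = 900, n_conserved_blocks = 6,
                           conserved_fraction = 0.4, divergence = 0.2,
                           seed = 2)
  blocks <- attr(p, "blocks")
  cons <- blocks[blocks$type == "conserved", ]
  for (b in seq_len(nrow(cons))) {
    frags <- substr(p$seq, cons$start[b], cons$end[b])
    expect_equal(length(unique(frags)), 1)
  }
  # variable blocks do differ at this divergence
  vb <- blocks[blocks$type == "variable", ][1, ]
  expect_gt(length(unique(substr(p$seq, vb$start, vb$end))), 1)

  # determinism
  expect_identical(p$seq,
                   make_reference_pool(5, length = 900,
                                       n_conserved_blocks = 6,
                                       conserved_fraction = 0.4,
                                       divergence = 0.2, seed = 2)$seq)
  # 10 variable blocks cannot fit in 8 variable bases
  expect_error(make_reference_pool(3, length = 20, n_conserved_blocks = 9,
                                   conserved_fraction = 0.6, seed = 1),
               "empty")
})

test_that("pairwise pool identity matches the analytic expectation", {
  # two species, half conserved, divergence d in the variable half:
  # E[identity] = cf + (1 - cf) * ((1-d)^2 + d^2/3)
  # (positionwise identity: the pool is substitution-only, same length)
  d <- 0.5; cf <- 0.5
  expected <- cf + (1 - cf) * ((1 - d)^2 + d^2 / 3)
  obs <- vapply(1:20, function(s) {
    p <- make_reference_pool(2, length = 1000, n_conserved_blocks = 5,
                             conserved_fraction = cf, divergence = d,
                             seed = s)
    mean(strsplit(p$seq[1], "")[[1]] == strsplit(p$seq[2], "")[[1]])
  }, numeric(1))
  # per-seed sd ~ 0.5*sqrt(p(1-p)/500) ~ 0.011; mean of 20 has sd ~ 0.0024
  expect_lt(abs(mean(obs) - expected), 4 * 0.0024)
})

test_that("communities are drawn without replacement with normalised log-normal abundances", {
  pool <- make_reference_pool(10, length = 500, n_conserved_blocks = 4,
                              seed = 3)
  prof1 <- sample_community(pool, 1, seed = 4)
  expect_equal(prof1$abundance, 1.0)

  prof0 <- sample_community(pool, 5, lognormal_sigma = 0, seed = 5)
  expect_equal(prof0$abundance, rep(0.2, 5))

  prof <- sample_community(pool, 8, lognormal_sigma = 1.5, seed = 6)
  expect_equal(sum(prof$abundance), 1.0, tolerance = 1e-9)
  expect_false(anyDuplicated(prof$source_id) > 0)
  expect_error(sample_community(pool, 11, seed = 1), "exceeds")
})

test_that("simulated reads are error-free substrings at rate 0 and deterministic", {
  pool <- make_reference_pool(4, length = 800, n_conserved_blocks = 4,
                              seed = 7)
  prof <- sample_community(pool, 2, seed = 8)
  r <- simulate_reads(prof, 5, read_len = 100, insert_mean = 250,
                      insert_sd = 20, error_rate = 0, seed = 9)
  expect_equal(nrow(r), 5)
  for (i in 1:5) {
    src <- strsplit(r$id[i], "|", fixed = TRUE)[[1]][2]
    s <- prof$seq[prof$source_id == src]
    expect_true(grepl(r$seq1[i], s, fixed = TRUE))
    expect_true(grepl(revcomp(r$seq2[i]), s, fixed = TRUE))
  }
  r2 <- simulate_reads(prof, 5, read_len = 100, insert_mean = 250,
                       insert_sd = 20, error_rate = 0, seed = 9)
  expect_identical(r, r2)                 # byte-identical under one seed
  expect_false(identical(
    r$seq1,
    simulate_reads(prof, 5, read_len = 100, insert_mean = 250,
                   insert_sd = 20, error_rate = 0, seed = 10)$seq1))
})

test_that("read counts per source follow the community abundances", {
  pool <- make_reference_pool(4, length = 800, n_conserved_blocks = 4,
                              seed = 10)
  prof <- sample_community(pool, 2, seed = 11)
  prof$abundance <- c(0.9, 0.1)
  r <- simulate_reads(prof, 10000, read_len = 100, insert_mean = 250,
                      insert_sd = 20, error_rate = 0, seed = 12)
  src <- vapply(strsplit(r$id, "|", fixed = TRUE), `[`, character(1), 2)
  n1 <- sum(src == prof$source_id[1])
  expect_lt(abs(n1 - 9000), 4 * sqrt(10000 * 0.9 * 0.1))
  expect_equal(length(src), 10000)        # conservation of read pairs
})

test_that("scenario bundles satisfy their reference-database invariants", {
  pool <- make_reference_pool(12, length = 700, n_conserved_blocks = 5,
                              divergence = 0.12, seed = 13)
  prof <- sample_community(pool, 4, seed = 14)

  a <- make_scenario("a", pool, prof, n_pairs = 50, read_len = 100,
                     insert_mean = 250, insert_sd = 20, seed = 15)
  expect_true(all(a$profile$seq %in% a$reference_db$seq))

  b <- make_scenario("b", pool, prof, n_pairs = 50, read_len = 100,
                     insert_mean = 250, insert_sd = 20, seed = 15)
  expect_identical(b$reference_db$id, pool$id)
  for (i in seq_len(nrow(b$profile))) {
    best <- max(vapply(pool$seq, function(s)
      align_global(b$profile$seq[i], s, band = 16)$identity, numeric(1)))
    expect_gte(best, 0.95)
    expect_lte(best, 0.99)
  }

  cc <- make_scenario("c", pool, prof, n_pairs = 50, read_len = 100,
                      insert_mean = 250, insert_sd = 20, seed = 15)
  expect_false(any(cc$profile$seq %in% cc$reference_db$seq))
  expect_false(any(cc$profile$source_id %in% cc$reference_db$id))
  expect_equal(nrow(cc$reference_db), nrow(pool) - nrow(prof))
})

test_that("scenario bundles write and read back from disk", {
  pool <- make_reference_pool(6, length = 600, n_conserved_blocks = 4,
                              seed = 16)
  prof <- sample_community(pool, 3, seed = 17)
  sc <- make_scenario("a", pool, prof, n_pairs = 20, read_len = 100,
                      insert_mean = 250, insert_sd = 20, seed = 18)
  d <- withr::local_tempdir()
  write_scenario(sc, d)
  expect_equal(read_fasta(file.path(d, "sources.fasta"))$seq,
               sc$profile$seq)
  expect_equal(nrow(read_fastq_pairs(file.path(d, "S1_1.fastq"),
                                     file.path(d, "S1_2.fastq"), "S1")),
               20)
  truth <- readr::read_tsv(file.path(d, "truth.tsv"),
                           show_col_types = FALSE)
  expect_equal(truth$abundance, sc$profile$abundance)
})
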