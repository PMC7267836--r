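# Read mapping: identity contract, pair logic, ambiguity, coverage
# statistics, unmapped-pool split.

test_that("coverage statistics match hand computation on a built fixture", {
  # contig of length 100; four 50-base reads at starts 0, 25, 50, 50:
  # mean coverage 200/100 = 2.0, every position covered
  withr::with_seed(90, {
    contig <- rand_seq(100)
    reads <- vapply(c(1, 26, 51, 51), function(s) substr(contig, s, s + 49),
                    character(1))
    pairs <- full_overlap_pairs(reads)
    m <- map_reads(pairs, tibble::tibble(id = "c1", seq = contig),
                   default_config())
    expect_equal(m$per_contig$mean_coverage, 2.0)
    expect_equal(m$per_contig$covered_fraction, 1.0)
    expect_equal(m$per_contig$unambig_reads, 4L)
    expect_equal(m$per_contig$ambig_read_mass, 0)
    expect_equal(m$per_sample$mapping_rate, 1.0)

    # a single 50-base read: mean coverage 0.5, half covered
    m1 <- map_reads(full_overlap_pairs(reads[1]),
                    tibble::tibble(id = "c1", seq = contig),
                    default_config())
    expect_equal(m1$per_contig$mean_coverage, 0.5)
    expect_equal(m1$per_contig$covered_fraction, 0.5)
  })
})

test_that("the identity filter separates mapped from unmapped reads", {
  withr::with_seed(91, {
    contig <- rand_seq(1000)
    good <- substr(contig, 101, 250)            # exact, identity 1
    near <- mutate_k(substr(contig, 301, 450), 2, seed = 92)  # 148/150
    bad <- mutate_k(substr(contig, 501, 650), 7, seed = 93)   # 143/150 = 0.953
    pairs <- full_overlap_pairs(c(good, near, bad))
    m <- map_reads(pairs, tibble::tibble(id = "c1", seq = contig),
                   default_config())
    # 0.987 >= idfilter 0.98 maps; 0.953 < 0.98 (and < minid) does not
    expect_equal(sort(m$mapped_pairs$pair_idx), c(1L, 2L))
    u <- split_unmapped(pairs, m)
    expect_equal(nrow(u), 1)
    expect_equal(u$seq1, pairs$seq1[3])
  })
})

test_that("reads from a conserved block map ambiguously with split mass", {
  contigs <- shared_block_contigs(block_len = 150, unique_len = 300)
  block_read <- substr(contigs$seq[1], 301, 440)  # inside the shared block
  uniq_read <- substr(contigs$seq[1], 51, 190)    # inside the unique part
  pairs <- full_overlap_pairs(c(block_read, uniq_read))
  m <- map_reads(pairs, contigs, default_config())
  f <- m$fragments
  expect_equal(sort(f$k[f$pair_idx == 1]), c(2L, 2L))   # tied on A and B
  expect_equal(f$contig_id[f$pair_idx == 2], "A")
  pc <- m$per_contig
  expect_equal(pc$unambig_reads[pc$contig_id == "A"], 1L)
  expect_equal(pc$ambig_read_mass[pc$contig_id == "A"], 0.5)
  expect_equal(pc$ambig_read_mass[pc$contig_id == "B"], 0.5)
  # conservation: unambig + ambig mass sums to mapped fragments
  expect_equal(sum(pc$unambig_reads) + sum(pc$ambig_read_mass),
               m$per_sample$mapped_reads)
})

test_that("unmerged pairs map only when both mates hit one contig on opposite strands", {
  withr::with_seed(94, {
    contig <- rand_seq(900)
    # a proper pair: insert 400, mates 150bp, no overlap -> unmerged
    frag <- substr(contig, 201, 600)
    p_good <- tibble::tibble(
      id = "good", seq1 = substr(frag, 1, 150),
      qual1 = strrep("?", 150),
      seq2 = revcomp(substr(frag, 251, 400)), qual2 = strrep("?", 150),
      sample = "S1")
    # a chimeric pair: mate 2 from elsewhere entirely
    p_bad <- tibble::tibble(
      id = "chimera", seq1 = substr(contig, 1, 150),
      qual1 = strrep("?", 150),
      seq2 = rand_seq(150), qual2 = strrep("?", 150), sample = "S1")
    pairs <- dplyr::bind_rows(p_good, p_bad)
    m <- map_reads(pairs, tibble::tibble(id = "c1", seq = contig),
                   default_config())
    expect_equal(m$mapped_pairs$pair_id, "good")
    expect_equal(nrow(split_unmapped(pairs, m)), 1)
    # both mates' aligned bases count toward coverage
    expect_equal(m$per_contig$mean_coverage, 300 / 900)
  })
})

test_that("every input pair lands in exactly one of mapped or unmapped", {
  withr::with_seed(95, {
    pool <- make_reference_pool(6, length = 600, n_conserved_blocks = 4,
                                seed = 96)
    prof <- sample_community(pool, 3, seed = 97)
    reads <- simulate_reads(prof, 300, read_len = 100, insert_mean = 250,
                            insert_sd = 20, error_rate = 0.01, seed = 98)
    contigs <- tibble::tibble(id = prof$source_id, seq = prof$seq)
    m <- map_reads(reads, contigs, default_config())
    u <- split_unmapped(reads, m)
    expect_equal(nrow(u) + nrow(m$mapped_pairs), nrow(reads))
    expect_length(intersect(u$id, m$mapped_pairs$pair_id), 0)
    # determinism: identical inputs give identical statistics
    m2 <- map_reads(reads, contigs, default_config())
    expect_identical(m$per_contig, m2$per_contig)
    expect_identical(m$per_sample, m2$per_sample)
  })
})

test_that("unhit contigs are reported with zero statistics", {
  withr::with_seed(99, {
    contigs <- tibble::tibble(id = c("hit", "miss"),
                              seq = c(rand_seq(300), rand_seq(300)))
    pairs <- full_overlap_pairs(substr(contigs$seq[1], 51, 200))
    m <- map_reads(pairs, contigs, default_config())
    miss <- m$per_contig[m$per_contig$contig_id == "miss", ]
    expect_equal(miss$mean_coverage, 0)
    expect_equal(miss$covered_fraction, 0)
    expect_equal(miss$unambig_reads, 0L)
  })
  expect_error(map_reads(full_overlap_pairs("ACGT"),
                         tibble::tibble(id = character(),
                                        seq = character())),
               "non-empty")
})
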