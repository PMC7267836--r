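# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; no files are read from disk.

rand_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# a read-pair row whose mates merge completely (mate 2 = revcomp of mate 1),
# so the pair maps as a single unit with the given sequence
full_overlap_pair <- function(seq, id = "p1", sample = "S1") {
  q <- strrep("?", nchar(seq))
  tibble::tibble(id = id, seq1 = seq, qual1 = q,
                 seq2 = riboloop::revcomp(seq), qual2 = q, sample = sample)
}

full_overlap_pairs <- function(seqs, ids = sprintf("p%03d", seq_along(seqs)),
                               sample = "S1") {
  dplyr::bind_rows(Map(full_overlap_pair, seqs, ids,
                       MoreArgs = list(sample = sample)))
}

# substitute exactly k positions of a sequence (deterministic under seed)
mutate_k <- function(seq, k, seed = 1) {
  withr::with_seed(seed, {
    ch <- strsplit(seq, "")[[1]]
    pos <- sample(seq_along(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  })
}

# tiny two-block community: two contigs sharing an identical conserved
# block, used for ambiguity fixtures
shared_block_contigs <- function(block_len = 120, unique_len = 200,
                                 seed = 42) {
  withr::with_seed(seed, {
    block <- paste(sample(c("A", "C", "G", "T"), block_len, TRUE),
                   collapse = "")
    u1 <- paste(sample(c("A", "C", "G", "T"), unique_len, TRUE),
                collapse = "")
    u2 <- paste(sample(c("A", "C", "G", "T"), unique_len, TRUE),
                collapse = "")
    tibble::tibble(id = c("A", "B"),
                   seq = c(paste0(u1, block), paste0(u2, block)))
  })
}
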