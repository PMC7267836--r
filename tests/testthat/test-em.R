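# EM assembler: posterior arithmetic, M-step updates, candidate merging,
# end-to-end assembly behaviour.

em_fixture <- function(n_refs = 2, len = 400, seed = 50) {
  withr::with_seed(seed, {
    refs <- tibble::tibble(id = sprintf("r%d", seq_len(n_refs)),
                           seq = replicate(n_refs, rand_seq(len)))
    refs
  })
}

test_that("E-step posteriors follow the stated likelihood ratio", {
  # two candidates with equal priors; a 150-base read matches candidate 1
  # exactly and candidate 2 with one mismatch: z1/z2 = (1-eps)/(eps/3)
  withr::with_seed(51, {
    c1 <- rand_seq(400)
    c2 <- paste0(substr(c1, 1, 199),
                 setdiff(c("A", "C", "G", "T"), substr(c1, 200, 200))[1],
                 substr(c1, 201, 400))
    refs <- tibble::tibble(id = c("c1", "c2"), seq = c(c1, c2))
    read <- substr(c1, 101, 250)          # covers the differing base
    pairs <- full_overlap_pair(read)
    cfg <- default_config()
    units <- pair_units(pairs, cfg)
    model <- em_initialize(units, refs, cfg)
    expect_equal(sort(model$candidates$id), c("c1", "c2"))
    expect_equal(model$candidates$prior, c(0.5, 0.5))
    eps <- 0.01
    model <- em_e_step(model, units, epsilon = eps)
    z <- model$posteriors
    z1 <- z$z[z$cand == "c1"]; z2 <- z$z[z$cand == "c2"]
    ratio <- (1 - eps) / (eps / 3)
    expect_equal(z1 / z2, ratio, tolerance = 1e-9)
    expect_equal(z1, ratio / (ratio + 1), tolerance = 1e-9)
    expect_equal(z1 + z2, 1.0, tolerance = 1e-12)

    # zero prior kills the posterior regardless of the alignment
    model$candidates$prior <- c(1, 0)
    model <- em_e_step(model, units, epsilon = eps)
    expect_equal(model$posteriors$z[model$posteriors$cand == "c1"], 1.0)
    expect_false("c2" %in% model$posteriors$cand)
  })
  expect_error(em_e_step(structure(list(), class = "riboloop_em"),
                         NULL, epsilon = 0.9), "epsilon")
})

test_that("a sole candidate absorbs all posterior mass", {
  refs <- em_fixture(1)
  reads <- full_overlap_pairs(
    vapply(c(1, 101, 201), function(s) substr(refs$seq[1], s, s + 149),
           character(1)))
  cfg <- default_config()
  units <- pair_units(reads, cfg)
  model <- em_initialize(units, refs, cfg)
  expect_equal(model$candidates$prior, 1.0)
  model <- em_e_step(model, units)
  expect_true(all(model$posteriors$z == 1.0))
  # total posterior mass equals the number of retained units
  expect_equal(sum(model$posteriors$z), length(model$retained))
})

test_that("M-step priors reflect posterior mass and prune dead candidates", {
  withr::with_seed(52, {
    refs <- em_fixture(2, seed = 53)      # unrelated references
    # 3 reads from r1, 1 read from r2, all unambiguous
    r1 <- vapply(c(1, 81, 161), function(s) substr(refs$seq[1], s, s + 149),
                 character(1))
    r2 <- substr(refs$seq[2], 51, 200)
    pairs <- full_overlap_pairs(c(r1, r2))
    cfg <- default_config()
    units <- pair_units(pairs, cfg)
    model <- em_initialize(units, refs, cfg)
    model <- em_e_step(model, units)
    model <- em_m_step(model, units, cfg)
    pri <- stats::setNames(model$candidates$prior, model$candidates$id)
    expect_equal(unname(pri["r1"]), 0.75, tolerance = 1e-9)
    expect_equal(unname(pri["r2"]), 0.25, tolerance = 1e-9)
    expect_equal(sum(model$candidates$prior), 1.0, tolerance = 1e-9)

    # a candidate with no aligned reads is pruned
    refs3 <- dplyr::bind_rows(refs, tibble::tibble(id = "r3",
                                                   seq = rand_seq(400)))
    model3 <- em_initialize(units, refs3, cfg)
    if ("r3" %in% model3$candidates$id) {
      model3 <- em_e_step(model3, units)
      model3 <- em_m_step(model3, units, cfg)
      expect_false("r3" %in% model3$candidates$id)
    } else succeed()
  })
})

test_that("consensus flips a base when weighted reads disagree with the reference", {
  withr::with_seed(54, {
    truth <- rand_seq(400)
    # reference differs from the truth at one position
    ref <- paste0(substr(truth, 1, 249),
                  setdiff(c("A", "C", "G", "T"),
                          substr(truth, 250, 250))[1],
                  substr(truth, 251, 400))
    refs <- tibble::tibble(id = "ref", seq = ref)
    reads <- full_overlap_pairs(
      vapply(c(150, 180, 210), function(s) substr(truth, s, s + 149),
             character(1)))
    cfg <- default_config()
    units <- pair_units(reads, cfg)
    model <- em_initialize(units, refs, cfg)
    model <- em_e_step(model, units)
    model <- em_m_step(model, units, cfg)
    expect_equal(substr(model$candidates$seq, 250, 250),
                 substr(truth, 250, 250))
    expect_identical(model$candidates$seq, truth)
  })
})

test_that("near-identical candidates merge into the higher-prior one", {
  withr::with_seed(55, {
    base <- rand_seq(400)
    cfg <- default_config()
    mk_model <- function(seqs, priors) {
      structure(list(
        candidates = tibble::tibble(id = sprintf("c%d", seq_along(seqs)),
                                    seq = seqs, prior = priors),
        hits = tibble::tibble(unit_idx = integer(), cand = character(),
                              score = numeric(), identity = numeric(),
                              matches = integer(), mismatches = integer(),
                              indels = integer(), tstart = integer(),
                              strand = integer()),
        z = NULL, posteriors = NULL, retained = integer(),
        stale = character(), unit_rc = character(), em_iteration = 0L,
        params = riboloop:::em_params(cfg)), class = "riboloop_em")
    }
    # identical pair: merged, priors summed
    m <- em_merge_similar(mk_model(c(base, base), c(0.6, 0.4)), 0.97)
    expect_equal(nrow(m$candidates), 1)
    expect_equal(m$candidates$prior, 1.0)
    expect_equal(m$candidates$id, "c1")   # higher prior wins

    # 95% identity pair: both kept at a 0.97 ceiling
    far <- mutate_k(base, 20, seed = 56)  # 380/400 = 0.95
    m2 <- em_merge_similar(mk_model(c(base, far), c(0.6, 0.4)), 0.97)
    expect_equal(nrow(m2$candidates), 2)

    # three mutually >= 97% candidates collapse to exactly one
    v1 <- mutate_k(base, 4, seed = 57)
    v2 <- mutate_k(base, 4, seed = 58)
    seqs <- c(base, v1, v2)
    idm <- outer(seq_along(seqs), seq_along(seqs), Vectorize(function(i, j)
      oracle_global(seqs[i], seqs[j])$identity))
    expect_true(all(idm >= 0.97))         # oracle confirms mutual similarity
    m3 <- em_merge_similar(mk_model(seqs, c(0.5, 0.3, 0.2)), 0.97)
    expect_equal(nrow(m3$candidates), 1)
    expect_equal(m3$candidates$prior, 1.0)
  })
})

test_that("assembly recovers a single source exactly from error-free reads", {
  withr::with_seed(60, {
    pool <- make_reference_pool(5, length = 600, n_conserved_blocks = 4,
                                seed = 61)
    prof <- sample_community(pool, 1, seed = 62)
    reads <- simulate_reads(prof, 400, read_len = 100, insert_mean = 250,
                            insert_sd = 20, error_rate = 0, seed = 63)
    cfg <- default_config()
    asm <- em_assemble(reads, pool, cfg, run_label = "t")
    expect_equal(nrow(asm$contigs), 1)
    expect_equal(asm$contigs$seq, prof$seq)
    expect_equal(asm$contigs$prior, 1.0)
    expect_true(startsWith(asm$contigs$id, "t_"))
  })
  # empty input propagates to an empty contig set
  expect_equal(nrow(em_assemble(NULL, em_fixture(2))$contigs), 0)
  p0 <- full_overlap_pairs(character(0))
  expect_equal(nrow(em_assemble(p0, em_fixture(2))$contigs), 0)
})

test_that("two distinct sources are recovered with priors near read fractions", {
  withr::with_seed(64, {
    # two references at <= 94% mutual identity, both in the database
    a <- rand_seq(500)
    b <- mutate_k(a, 50, seed = 65)       # ~90% identity
    expect_lte(oracle_global(a, b)$identity, 0.94)
    refs <- tibble::tibble(id = c("srcA", "srcB"), seq = c(a, b))
    prof <- tibble::tibble(source_id = refs$id, seq = refs$seq,
                           abundance = c(0.75, 0.25))
    reads <- simulate_reads(prof, 1200, read_len = 100, insert_mean = 250,
                            insert_sd = 20, error_rate = 0, seed = 66)
    cfg <- default_config()
    asm <- em_assemble(reads, refs, cfg)
    expect_equal(nrow(asm$contigs), 2)
    expect_setequal(asm$contigs$seq, refs$seq)
    src <- vapply(strsplit(reads$id, "|", fixed = TRUE), `[`,
                  character(1), 2)
    frac_a <- mean(src == "srcA")
    pri_a <- asm$contigs$prior[asm$contigs$seq == a]
    expect_lt(abs(pri_a - frac_a), 0.05)
  })
})

test_that("retained reads shrink monotonically and priors stay normalised", {
  withr::with_seed(67, {
    pool <- make_reference_pool(6, length = 600, n_conserved_blocks = 4,
                                seed = 68)
    prof <- sample_community(pool, 3, seed = 69)
    reads <- simulate_reads(prof, 300, read_len = 100, insert_mean = 250,
                            insert_sd = 20, error_rate = 0.01, seed = 70)
    cfg <- default_config()
    units <- pair_units(reads, cfg)
    model <- em_initialize(units, pool, cfg)
    prev <- length(model$retained)
    for (t in 1:5) {
      model <- em_e_step(model, units, cfg$em_epsilon)
      expect_lte(length(model$retained), prev)
      expect_equal(sum(model$posteriors$z), length(model$retained),
                   tolerance = 1e-6)
      prev <- length(model$retained)
      model <- em_m_step(model, units, cfg)
      expect_equal(sum(model$candidates$prior), 1.0, tolerance = 1e-9)
    }
  })
})
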