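# Synthetic rRNA-like communities and paired-end read simulation.
#
# The generator emulates the statistical structure of SSU rRNA benchmark
# communities: a pool of full-length references sharing conserved blocks
# interleaved with divergent variable blocks, source communities drawn with
# log-normal abundances, and substitution-error paired-end reads.  Three
# reference-database scenarios are supported: sources present in the
# database (a), sources 95-99% similar to it (b), sources absent from it (c).

#' Generate an rRNA-like reference pool
#'
#' One random template of the given length is generated; conserved blocks
#' (totalling `conserved_fraction` of the length, evenly interleaved with
#' variable blocks) are shared verbatim by all species, while variable
#' blocks are independently mutated per species at per-base substitution
#' rate `divergence`. The conserved/variable architecture reproduces the
#' ambiguous-mapping behaviour of real SSU rRNA genes.
#'
#' @param n_species Number of reference sequences (>= 2).
#' @param length Sequence length in bases.
#' @param n_conserved_blocks Number of conserved blocks (variable blocks
#'   surround them, so there are `n_conserved_blocks + 1` variable blocks).
#' @param conserved_fraction Fraction of the length that is conserved,
#'   strictly between 0 and 1.
#' @param divergence Per-base substitution rate applied independently per
#'   species inside variable blocks.
#' @param seed RNG seed; the pool is a pure function of its arguments.
#' @return A tibble with columns `id`, `seq`, and attributes `blocks`
#'   (tibble of block type/start/end, 1-based closed) and `template`.
#' @export
#' @examples
#' pool <- make_reference_pool(3, length = 300, seed = 1)
#' attr(pool, "blocks")
make_reference_pool <- function(n_species, length = 1500,
                                n_conserved_blocks = 9,
                                conserved_fraction = 0.4,
                                divergence = 0.12, seed = 1) {
  stopifnot(n_species >= 2, length >= 2,
            conserved_fraction > 0, conserved_fraction < 1,
            n_conserved_blocks >= 1, divergence >= 0, divergence <= 1)
  ncb <- as.integer(n_conserved_blocks)
  cons_total <- round(conserved_fraction * length)
  var_total <- length - cons_total
  nvb <- ncb + 1L
  if (cons_total < ncb) stop("conserved blocks would be empty")
  if (var_total < nvb)
    stop("parameters imply empty variable blocks")
  split_even <- function(total, k) {
    base <- total %/% k
    rep(base, k) + c(rep(1L, total - base * k), rep(0L, k - (total - base * k)))
  }
  clen <- split_even(cons_total, ncb)
  vlen <- split_even(var_total, nvb)
  # layout: V1 C1 V2 C2 ... C_ncb V_{ncb+1}
  types <- character(0); lens <- integer(0)
  for (b in seq_len(ncb)) {
    types <- c(types, "variable", "conserved")
    lens <- c(lens, vlen[b], clen[b])
  }
  types <- c(types, "variable"); lens <- c(lens, vlen[nvb])
  ends <- cumsum(lens)
  blocks <- tibble(type = types, start = ends - lens + 1L, end = ends)
  var_pos <- unlist(Map(seq, blocks$start[blocks$type == "variable"],
                        blocks$end[blocks$type == "variable"]))
  with_seed(seed, {
    template <- random_seq(length)
    seqs <- character(n_species)
    tchars <- strsplit(template, "")[[1]]
    for (s in seq_len(n_species)) {
      chars <- tchars
      if (divergence > 0) {
        hit <- var_pos[runif(length(var_pos)) < divergence]
        if (length(hit)) {
          cur <- chars[hit]
          off <- sample.int(3L, length(hit), replace = TRUE)
          code <- (match(cur, DNA_BASES) - 1L + off) %% 4L
          chars[hit] <- DNA_BASES[code + 1L]
        }
      }
      seqs[s] <- paste(chars, collapse = "")
    }
    out <- tibble(id = sprintf("ref_%03d", seq_len(n_species)), seq = seqs)
    attr(out, "blocks") <- blocks
    attr(out, "template") <- template
    out
  })
}

#' Draw a ground-truth community from a reference pool
#'
#' Sources are drawn without replacement; relative abundances are i.i.d.
#' log-normal draws normalised to sum to one (`lognormal_sigma = 0`
#' degenerates to uniform abundances).
#'
#' @param pool Reference pool tibble (columns `id`, `seq`).
#' @param n_sources Number of sources to draw (<= `nrow(pool)`).
#' @param lognormal_mu,lognormal_sigma Log-normal parameters on the log
#'   scale.
#' @param seed RNG seed.
#' @return A community profile tibble with columns `source_id`, `seq`,
#'   `abundance` (summing to 1).
#' @export
sample_community <- function(pool, n_sources, lognormal_mu = 0,
                             lognormal_sigma = 1.5, seed = 1) {
  stopifnot(all(c("id", "seq") %in% names(pool)), n_sources >= 1)
  if (n_sources > nrow(pool))
    stop("n_sources exceeds the pool size (", nrow(pool), ")")
  with_seed(seed, {
    idx <- sample.int(nrow(pool), n_sources)
    ab <- if (lognormal_sigma == 0) rep(exp(lognormal_mu), n_sources)
          else rlnorm(n_sources, lognormal_mu, lognormal_sigma)
    tibble(source_id = pool$id[idx], seq = pool$seq[idx],
           abundance = ab / sum(ab))
  })
}

#' Simulate paired-end reads from a community
#'
#' Each pair's source is drawn from the community abundances; the fragment
#' start is uniform over valid positions and the insert length is
#' `round(Normal(insert_mean, insert_sd))` clamped to
#' `[read_len, source length]`. Mate 1 is the fragment's 5' read; mate 2 is
#' the reverse complement of its 3' read. Substitution errors are applied
#' per base with probability `error_rate` (uniform over the three other
#' bases); qualities are constant Phred 30. Pair ids encode the source and
#' fragment coordinates as ground truth.
#'
#' @param profile Community profile (see [sample_community()]).
#' @param n_pairs Number of read pairs.
#' @param read_len Read length in bases.
#' @param insert_mean,insert_sd Insert-size distribution (bases).
#' @param error_rate Per-base substitution probability.
#' @param sample Sample label.
#' @param seed RNG seed.
#' @return A read-pair tibble (see [read_fastq_pairs()]).
#' @export
simulate_reads <- function(profile, n_pairs, read_len = 150,
                           insert_mean = 350, insert_sd = 35,
                           error_rate = 0.002, sample = "S1", seed = 1) {
  stopifnot(all(c("source_id", "seq", "abundance") %in% names(profile)),
            n_pairs >= 1, insert_mean >= read_len, insert_sd >= 0,
            error_rate >= 0, error_rate < 1)
  srclen <- nchar(profile$seq)
  if (any(srclen <= insert_mean + 4 * insert_sd))
    stop("all sources must be longer than insert_mean + 4*insert_sd")
  with_seed(seed, {
    src <- sample.int(nrow(profile), n_pairs, replace = TRUE,
                      prob = profile$abundance)
    ins <- round(rnorm(n_pairs, insert_mean, insert_sd))
    ins <- pmin(pmax(ins, read_len), srclen[src])
    start <- 1L + floor(runif(n_pairs) * (srclen[src] - ins + 1))
    frag <- substr(profile$seq[src], start, start + ins - 1)
    m1 <- substr(frag, 1, read_len)
    m2 <- revcomp(substr(frag, ins - read_len + 1, ins))
    m1 <- add_substitutions(m1, error_rate)
    m2 <- add_substitutions(m2, error_rate)
    q <- strrep(rawToChar(as.raw(30 + 33)), read_len)
    tibble(id = sprintf("p%07d|%s|%d-%d", seq_len(n_pairs),
                        profile$source_id[src], start, start + ins - 1L),
           seq1 = m1, qual1 = q, seq2 = m2, qual2 = q, sample = sample)
  })
}

# max identity of `seq` against each database sequence (banded global with
# shared-kmer prefilter); returns the vector of identities
db_identities <- function(seq, db_seqs, k = 13, floor_identity = 0.90) {
  pre <- cpp_shared_kmer_frac(c(seq, db_seqs), as.integer(k))[1, -1]
  thr <- kmer_prefilter_threshold(floor_identity, k)
  ids <- numeric(length(db_seqs))
  for (j in seq_along(db_seqs)) {
    if (pre[j] < thr) next
    band <- abs(nchar(seq) - nchar(db_seqs[j])) + 16L
    r <- cpp_align_global(seq, db_seqs[j], 1, -1, -2, band)
    ids[j] <- identity_of(r$matches, r$mismatches, r$indels)
  }
  ids
}

#' Build a benchmark scenario bundle
#'
#' Scenario `a` keeps the sources verbatim in the reference database;
#' scenario `b` replaces each source by a mutated copy whose verified
#' global identity to its nearest database entry lies in `identity_band`
#' (mutation rates are rejection-sampled until the band is hit); scenario
#' `c` removes the sources from the reference database. Reads are then
#' simulated from the (possibly mutated) sources.
#'
#' @param scenario One of `"a"`, `"b"`, `"c"`.
#' @param pool Reference pool the profile was drawn from.
#' @param profile Community profile drawn from `pool`.
#' @param n_pairs,read_len,insert_mean,insert_sd,error_rate,sample Read
#'   simulation parameters (see [simulate_reads()]).
#' @param identity_band Scenario-b target band for nearest-database
#'   identity.
#' @param max_attempts Scenario-b rejection-sampling bound per source.
#' @param seed RNG seed (reads use `seed + 1`).
#' @return A `riboloop_scenario` list: `scenario`, `profile`,
#'   `reference_db`, `reads`.
#' @export
make_scenario <- function(scenario = c("a", "b", "c"), pool, profile,
                          n_pairs = 1e5, read_len = 150, insert_mean = 350,
                          insert_sd = 35, error_rate = 0.002, sample = "S1",
                          identity_band = c(0.95, 0.99), max_attempts = 50,
                          seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(all(profile$source_id %in% pool$id))
  reference_db <- pool[, c("id", "seq")]
  if (scenario == "b") {
    profile <- with_seed(seed, {
      for (i in seq_len(nrow(profile))) {
        done <- FALSE
        for (att in seq_len(max_attempts)) {
          rate <- runif(1, 1 - identity_band[2], 1 - identity_band[1])
          mut <- add_substitutions(profile$seq[i], rate)
          best <- max(db_identities(mut, pool$seq))
          if (best >= identity_band[1] && best <= identity_band[2]) {
            profile$seq[i] <- mut
            done <- TRUE
            break
          }
        }
        if (!done)
          stop("scenario b: could not hit the identity band for source ",
               profile$source_id[i], " in ", max_attempts, " attempts")
      }
      profile
    })
  } else if (scenario == "c") {
    reference_db <- filter(reference_db, !.data$id %in% profile$source_id)
    if (nrow(reference_db) == 0)
      stop("scenario c: removing the sources empties the reference database")
  }
  reads <- simulate_reads(profile, n_pairs, read_len, insert_mean,
                          insert_sd, error_rate, sample, seed = seed + 1)
  structure(list(scenario = scenario, profile = profile,
                 reference_db = reference_db, reads = reads),
            class = "riboloop_scenario")
}

#' Write a scenario bundle to disk
#'
#' Writes `sources.fasta`, `reference_db.fasta`, per-sample FASTQ pairs and
#' the ground-truth abundance TSV (`truth.tsv`: source_id, abundance).
#'
#' @param bundle A `riboloop_scenario` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  stopifnot(inherits(bundle, "riboloop_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(tibble(id = bundle$profile$source_id,
                     seq = bundle$profile$seq),
              file.path(dir, "sources.fasta"))
  write_fasta(bundle$reference_db, file.path(dir, "reference_db.fasta"))
  for (s in unique(bundle$reads$sample)) {
    p <- filter(bundle$reads, .data$sample == s)
    write_fastq_pairs(p, file.path(dir, paste0(s, "_1.fastq")),
                      file.path(dir, paste0(s, "_2.fastq")))
  }
  readr::write_tsv(bundle$profile[, c("source_id", "abundance")],
                   file.path(dir, "truth.tsv"))
  invisible(dir)
}
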