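# User-facing alignment operations over the compiled kernel.
#
# Identity is defined as matches / alignment columns (gap-inclusive),
# the BLAST-style arithmetic used by common dereplication tools. Non-ACGT
# characters (N) never match, including against themselves.

hit_tibble <- function(query_id, target_id, matches, mismatches, indels,
                       score, target_start, target_end, strand) {
  tibble(query_id = query_id, target_id = target_id,
         identity = identity_of(matches, mismatches, indels),
         matches = as.integer(matches), mismatches = as.integer(mismatches),
         indels = as.integer(indels), score = score,
         target_start = as.integer(target_start),
         target_end = as.integer(target_end), strand = strand)
}

#' Global (end-to-end) pairwise alignment
#'
#' Needleman-Wunsch alignment under linear gap penalties with a fixed
#' deterministic tie-break (at equal score: match/mismatch diagonal, then
#' gap in `b`, then gap in `a`). `band` restricts the explored offset
#' `j - i` to within `band` of the corner-to-corner diagonal; the default
#' (`NULL`) explores the full matrix.
#'
#' @param a,b Nucleotide sequences (single strings), both non-empty.
#' @param match,mismatch,gap Linear alignment scores.
#' @param band Optional half-width of the alignment band; `NULL` for exact
#'   full-matrix alignment.
#' @param query_id,target_id Labels carried into the result.
#' @return A one-row alignment tibble with `identity`, `matches`,
#'   `mismatches`, `indels`, `score`, `target_start`, `target_end`,
#'   `strand`.
#' @export
#' @examples
#' align_global("ACGTACGTAC", "ACGTACGTAT")$identity  # 0.9
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2,
                         band = NULL, query_id = "a", target_id = "b") {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  r <- cpp_align_global(a, b, match, mismatch, gap,
                        if (is.null(band)) -1L else as.integer(band))
  hit_tibble(query_id, target_id, r$matches, r$mismatches, r$indels,
             r$score, 0L, nchar(b), "+")
}

#' Glocal (read-in-target) alignment with an indel bound
#'
#' The read is consumed end-to-end against the best-scoring window of the
#' target; target overhangs are free. The alignment may contain at most
#' `max_indel` indel columns. Both strands are tried (best kept, ties
#' prefer `+`).
#'
#' @param read,target Nucleotide sequences (single strings).
#' @param max_indel Maximum number of indel columns in the alignment.
#' @param match,mismatch,gap Linear alignment scores.
#' @param both_strands Also try the reverse complement of `read`.
#' @param query_id Label carried into the result.
#' @return A one-row alignment tibble, or a zero-row tibble when no
#'   alignment within the indel bound exists (e.g. the read is longer than
#'   the target plus `max_indel`).
#' @export
#' @examples
#' align_glocal("CGTA", "AACGTAAA")$target_start  # 2
align_glocal <- function(read, target, max_indel = 1, match = 1,
                         mismatch = -1, gap = -2, both_strands = TRUE,
                         query_id = "read") {
  stopifnot(is.character(read), is.character(target),
            length(read) == 1, length(target) == 1)
  none <- hit_tibble(character(), character(), integer(), integer(),
                     integer(), numeric(), integer(), integer(), character())
  if (nchar(read) == 0 || nchar(target) == 0) return(none)
  if (nchar(read) > nchar(target) + max_indel) return(none)
  fw <- cpp_align_glocal(read, target, match, mismatch, gap,
                         as.integer(max_indel))
  best <- NULL; strand <- "+"
  if (isTRUE(fw$found)) best <- fw
  if (both_strands) {
    rv <- cpp_align_glocal(revcomp(read), target, match, mismatch, gap,
                           as.integer(max_indel))
    if (isTRUE(rv$found) && (is.null(best) || rv$score > best$score)) {
      best <- rv; strand <- "-"
    }
  }
  if (is.null(best)) return(none)
  hit_tibble(query_id, "target", best$matches, best$mismatches, best$indels,
             best$score, best$tstart, best$tend, strand)
}

#' Build a k-mer seed index over target sequences
#'
#' @param targets A data frame with columns `id`, `seq`.
#' @param k k-mer size (8-31; default 13).
#' @return A `riboloop_seed_index` object.
#' @export
seed_index <- function(targets, k = 13) {
  stopifnot(all(c("id", "seq") %in% names(targets)), k >= 8, k <= 31)
  structure(list(targets = as_tibble(targets[, c("id", "seq")]),
                 k = as.integer(k)),
            class = "riboloop_seed_index")
}

#' Seed-count candidate prefilter
#'
#' Returns the targets sharing at least `minhits` distinct k-mer positions
#' with the read (either strand, positions restricted to a consistent
#' diagonal band), i.e. the candidate set that full alignment would then be
#' run against.
#'
#' @param read A single read sequence.
#' @param index A [seed_index()] object.
#' @param minhits Minimum number of distinct seed positions.
#' @param max_indel Diagonal tolerance when clustering seed hits.
#' @return Character vector of candidate target ids.
#' @export
seeded_candidates <- function(read, index, minhits = 2, max_indel = 1) {
  stopifnot(inherits(index, "riboloop_seed_index"))
  idx <- cpp_seed_candidates(read, index$targets$seq, index$k,
                             as.integer(minhits), as.integer(max_indel), TRUE)
  index$targets$id[idx]
}

# All-pairs identity matrix via banded global alignment with a shared-kmer
# prefilter; pairs failing the prefilter get identity 0 (they provably
# cannot reach `min_identity`).  Used by merge_similar / scenario checks.
pairwise_identity <- function(seqs, min_identity, k = 13, band_extra = 16,
                              match = 1, mismatch = -1, gap = -2) {
  n <- length(seqs)
  out <- diag(1, n)
  if (n < 2) return(out)
  pre <- cpp_shared_kmer_frac(seqs, as.integer(k))
  thr <- kmer_prefilter_threshold(min_identity, k)
  len <- nchar(seqs)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (pre[i, j] < thr) next
      band <- abs(len[i] - len[j]) + band_extra
      r <- cpp_align_global(seqs[i], seqs[j], match, mismatch, gap,
                            as.integer(band))
      out[i, j] <- out[j, i] <- identity_of(r$matches, r$mismatches, r$indels)
    }
  }
  out
}
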