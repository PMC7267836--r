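# Overlap-based dereplication: greedy longest-first absorption of contigs
# into representatives, keeping the longest sequence per cluster.

#' Dereplicate contigs against an existing set
#'
#' New contigs are concatenated to the existing representatives, sorted by
#' descending length (ties: earlier iteration of origin, then ascending
#' id), and scanned greedily: a contig is a duplicate of an already
#' accepted representative when the glocal alignment of the shorter within
#' the longer has identity at least `min_identity` AND at most `max_edits`
#' indel columns (both strands tried). Duplicates are absorbed; survivors
#' are renamed `contig_<k>` in scan order.
#'
#' @param existing Existing contig tibble (columns `id`, `seq`, optionally
#'   `iteration`, `original_id`); may be `NULL` or empty.
#' @param incoming Incoming contig tibble (columns `id`, `seq`, optionally
#'   `iteration`).
#' @param min_identity Duplicate identity threshold (default 0.99).
#' @param max_edits Maximum indel columns in a duplicate alignment
#'   (default 5).
#' @param config Alignment scores and seed k (see [default_config()]).
#' @return A list with `contigs` (the dereplicated set, renamed, with
#'   provenance columns `iteration`, `original_id`, `length`) and
#'   `novel_count` (accepted representatives originating from `incoming`).
#' @export
dereplicate <- function(existing, incoming, min_identity = 0.99,
                        max_edits = 5, config = default_config()) {
  norm <- function(x, origin) {
    if (is.null(x) || nrow(x) == 0)
      return(tibble(id = character(), seq = character(),
                    iteration = integer(), original_id = character(),
                    origin = character()))
    x <- as_tibble(x)
    if (!"iteration" %in% names(x)) x$iteration <- NA_integer_
    if (!"original_id" %in% names(x)) x$original_id <- x$id
    tibble(id = x$id, seq = x$seq, iteration = as.integer(x$iteration),
           original_id = x$original_id, origin = origin)
  }
  all <- bind_rows(norm(existing, "existing"), norm(incoming, "incoming"))
  if (nrow(all) == 0)
    return(list(contigs = tibble(id = character(), seq = character(),
                                 length = integer(), iteration = integer(),
                                 original_id = character(),
                                 novel = logical()),
                novel_count = 0L))
  all$length <- nchar(all$seq)
  iter_key <- ifelse(is.na(all$iteration), .Machine$integer.max,
                     all$iteration)
  all <- all[order(-all$length, iter_key, all$id), ]
  # shared-kmer prefilter: a duplicate at >= min_identity must share kmers
  pre <- cpp_shared_kmer_frac(all$seq, as.integer(config$seed_k))
  thr <- kmer_prefilter_threshold(min_identity, config$seed_k)
  reps <- integer(0)
  is_dup <- logical(nrow(all))
  for (i in seq_len(nrow(all))) {
    for (r in reps) {
      if (pre[r, i] < thr) next
      if (is_duplicate(all$seq[i], all$seq[r], min_identity, max_edits,
                       config)) {
        is_dup[i] <- TRUE
        break
      }
    }
    if (!is_dup[i]) reps <- c(reps, i)
  }
  out <- all[reps, ]
  out$novel <- out$origin == "incoming"
  out$id <- sprintf("contig_%d", seq_len(nrow(out)))
  list(contigs = out[, c("id", "seq", "length", "iteration",
                         "original_id", "novel")],
       novel_count = as.integer(sum(out$novel)))
}

# duplicate criterion: glocal of the shorter within the longer, identity >=
# min_identity AND indel columns <= max_edits, either strand
is_duplicate <- function(short, long, min_identity, max_edits, config) {
  for (q in c(short, cpp_revcomp(short))) {
    r <- cpp_align_glocal(q, long, config$align_match, config$align_mismatch,
                          config$align_gap, as.integer(max_edits))
    if (isTRUE(r$found) &&
        identity_of(r$matches, r$mismatches, r$indels) >= min_identity &&
        r$indels <= max_edits)
      return(TRUE)
  }
  FALSE
}
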