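# Stringent read mapping against contigs, mapping statistics, and the
# unmapped-pool split.
#
# Each read unit (merged pair, or each mate of an unmerged pair) is seeded
# (minhits shared k-mers), glocally aligned (at most maxindel indel
# columns), with candidate hits below `map_minid` discarded during search.
# A unit is MAPPED iff its best identity reaches `map_idfilter`; an
# unmerged pair is MAPPED iff both mates map to the same contig on opposite
# strands. A mapped fragment's hit set is every contig tied with its best
# alignment score; ambiguous fragments (hit set > 1) contribute mass 1/k to
# each of the k tied contigs so that per-sample abundance columns sum to
# the mapping rate exactly.

#' Map read pairs against a contig set
#'
#' @param pairs Read-pair tibble (see [read_fastq_pairs()]).
#' @param contigs Contig tibble with columns `id`, `seq` (non-empty).
#' @param config A [default_config()] object; uses the `map_*`, `seed_k`,
#'   `merge_*` and alignment-score fields.
#' @param stats Compute per-contig coverage/abundance statistics; the
#'   iterative loop turns this off since it only needs the mapped/unmapped
#'   split.
#' @return A `riboloop_mapping` object: `fragments` (one row per mapped
#'   fragment x tied contig, with the tie count `k`), `mapped_pairs`,
#'   `per_contig` statistics (`mean_coverage`, `covered_fraction`,
#'   `unambig_reads`, `ambig_read_mass`; every contig reported, zeros when
#'   unhit), and `per_sample` statistics (`total_reads`, `mapped_reads`,
#'   `mapping_rate`, counted in fragments = pairs).
#' @export
map_reads <- function(pairs, contigs, config = default_config(),
                      stats = TRUE) {
  validate_pairs(pairs)
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  if (nrow(contigs) == 0) stop("map_reads requires a non-empty contig set")
  units <- pair_units(pairs, config)
  # mode 1: the kernel returns only best-score tie rows of units whose best
  # identity reaches the idfilter (i.e. MAPPED units).  When only the
  # mapped/unmapped split is needed the search floor is raised to the
  # idfilter: hits below it cannot make a unit mapped.
  minid <- if (stats) config$map_minid
           else max(config$map_minid, config$map_idfilter)
  raw <- cpp_map_reads(units$seq, contigs$seq, as.integer(config$seed_k),
                       as.integer(config$map_minhits),
                       as.integer(config$map_maxindel), minid,
                       config$align_match, config$align_mismatch,
                       config$align_gap, TRUE, 1L, config$map_idfilter)
  fr <- cpp_pair_fragments(raw$query, raw$target, raw$strand, raw$tstart,
                           raw$tend, raw$matches, raw$mismatches,
                           units$pair_idx, units$mate, nrow(pairs))
  frag <- tibble(pair_idx = fr$pair_idx, target = fr$target, k = fr$k)
  mapped_idx <- unique(frag$pair_idx)      # already in ascending pair order
  mapped_pairs <- tibble(pair_idx = mapped_idx,
                         pair_id = pairs$id[mapped_idx],
                         sample = pairs$sample[mapped_idx])
  is_mapped <- logical(nrow(pairs))
  is_mapped[mapped_idx] <- TRUE
  per_sample <- tibble(sample = pairs$sample, mapped = is_mapped) |>
    group_by(.data$sample) |>
    summarise(total_reads = n(), mapped_reads = sum(.data$mapped),
              .groups = "drop") |>
    mutate(mapping_rate = .data$mapped_reads / .data$total_reads)
  per_contig <- NULL
  if (stats) {
    cov_rows <- tibble(target = fr$cov_target, tstart = fr$cov_tstart,
                       tend = fr$cov_tend, albases = fr$cov_albases)
    per_contig <- contig_stats(contigs, cov_rows, frag)
  }
  frag$contig_id <- contigs$id[frag$target]
  frag$sample <- pairs$sample[frag$pair_idx]
  structure(list(fragments = frag, mapped_pairs = mapped_pairs,
                 per_contig = per_contig, per_sample = per_sample,
                 n_pairs = nrow(pairs), contig_ids = contigs$id),
            class = "riboloop_mapping")
}

covered_fraction_of <- function(L, tstart, tend) {
  if (length(tstart) == 0) return(0)
  add <- tabulate(pmin(tstart + 1L, L), nbins = L)
  rem <- tabulate(tend + 1L, nbins = L)   # tend == L falls off the end
  mean(cumsum(add - rem) > 0)
}

contig_stats <- function(contigs, cov_rows, frag) {
  L <- nchar(contigs$seq)
  n <- nrow(contigs)
  mean_cov <- numeric(n); covered <- numeric(n)
  if (nrow(cov_rows) > 0) {
    ab <- tapply(cov_rows$albases, factor(cov_rows$target, levels = seq_len(n)),
                 sum, default = 0)
    mean_cov <- as.numeric(ab) / L
    by_t <- split(seq_len(nrow(cov_rows)), cov_rows$target)
    for (t in names(by_t)) {
      ti <- as.integer(t)
      rows <- by_t[[t]]
      covered[ti] <- covered_fraction_of(L[ti], cov_rows$tstart[rows],
                                         cov_rows$tend[rows])
    }
  }
  unamb <- integer(n); amb <- numeric(n)
  if (nrow(frag) > 0) {
    f1 <- frag[frag$k == 1L, ]
    fk <- frag[frag$k > 1L, ]
    if (nrow(f1) > 0) {
      tu <- table(factor(f1$target, levels = seq_len(n)))
      unamb <- as.integer(tu)
    }
    if (nrow(fk) > 0) {
      ta <- tapply(1 / fk$k, factor(fk$target, levels = seq_len(n)),
                   sum, default = 0)
      amb <- as.numeric(ta)
    }
  }
  tibble(contig_id = contigs$id, length = L, mean_coverage = mean_cov,
         covered_fraction = covered, unambig_reads = unamb,
         ambig_read_mass = amb)
}

#' Extract the unmapped read pool
#'
#' Returns exactly the read pairs whose fragments were not MAPPED in
#' `mapping` (which must come from [map_reads()] on the same `pairs`
#' table), preserving input order.
#'
#' @param pairs The read-pair tibble that was mapped.
#' @param mapping The corresponding `riboloop_mapping`.
#' @return The unmapped subset of `pairs`.
#' @export
split_unmapped <- function(pairs, mapping) {
  stopifnot(inherits(mapping, "riboloop_mapping"),
            nrow(pairs) == mapping$n_pairs)
  if (nrow(mapping$mapped_pairs) == 0) return(pairs)
  pairs[-mapping$mapped_pairs$pair_idx, , drop = FALSE]
}

#' Write per-sample mapping statistics to TSV
#'
#' @param mapping A `riboloop_mapping` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mapping_stats <- function(mapping, path) {
  readr::write_tsv(mapping$per_contig, path)
  invisible(path)
}
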