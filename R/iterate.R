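# The iterative reconstruction loop: subsample the unmapped pool, EM
# sub-assembly, dereplication into the accumulating contig set, mapping of
# the whole pool against the contigs, pool shrinkage, termination.

#' Subsample read pairs without replacement
#'
#' Returns the whole pool when it holds at most `n` pairs; otherwise a
#' uniform random subset of `n` pairs (pairs kept intact, original order
#' preserved). Deterministic given `seed`.
#'
#' @param pool Read-pair tibble.
#' @param n Number of pairs to draw.
#' @param seed RNG seed.
#' @return A read-pair tibble with `min(n, nrow(pool))` rows.
#' @export
subsample_pairs <- function(pool, n, seed) {
  stopifnot(n >= 1)
  if (nrow(pool) <= n) return(pool)
  with_seed(seed, {
    idx <- sort(sample.int(nrow(pool), n))
    pool[idx, , drop = FALSE]
  })
}

#' Run the iterative reconstruction loop
#'
#' Per iteration `t`: subsample `n = config$sampling_num` pairs from the
#' unmapped pool `U` (seed `base_seed + t`), EM-assemble the subsample
#' against the reference database, dereplicate the new contigs into the
#' accumulating set `C`, map all of `U` against `C`, and shrink `U` to the
#' unmapped remainder. Termination is checked after each iteration in the
#' order: (ii) pool exhausted (`|U| < n`); (iii) low novelty
#' (`novel < novel_fraction_threshold * |C|`), which triggers ONE extra
#' iteration with subsample size `2n` before stopping; (i) the
#' `max_iterations` cap. The extra iteration cannot trigger another one,
#' so at most `max_iterations + 1` iterations run.
#'
#' @param all_reads Pooled read-pair tibble across samples.
#' @param reference_db Reference tibble (`id`, `seq`).
#' @param config A [default_config()] object.
#' @param verbose Print a per-iteration log line.
#' @return A `riboloop_run` object: `contigs` (the pre-filtering contig
#'   set), `unmapped` (the final pool), `trace` (one row per iteration:
#'   seed, subsample size, contig/novel counts, pool sizes, termination
#'   reason), and the `config`.
#' @export
run_iterations <- function(all_reads, reference_db,
                           config = default_config(), verbose = FALSE) {
  empty_trace <- tibble(iteration = integer(), seed_used = integer(),
                        subsample_size_used = integer(),
                        assembled_contigs = integer(),
                        contig_count = integer(), novel_count = integer(),
                        unmapped_before = integer(),
                        unmapped_count = integer(),
                        termination_reason = character())
  out <- function(contigs, unmapped, trace)
    structure(list(contigs = contigs, unmapped = unmapped,
                   trace = trace, config = config),
              class = "riboloop_run")
  C <- NULL
  if (is.null(all_reads) || nrow(all_reads) == 0)
    return(out(dereplicate(NULL, NULL, config = config)$contigs,
               all_reads, empty_trace))
  validate_pairs(all_reads)
  U <- all_reads
  n <- config$sampling_num
  trace <- list()
  t <- 0L
  pending_extra <- FALSE
  repeat {
    t <- t + 1L
    size <- if (pending_extra) 2L * n else n
    seed_t <- as.integer(config$base_seed + t)
    S <- subsample_pairs(U, size, seed_t)
    asm <- em_assemble(S, reference_db, config,
                       run_label = paste0("it", t))
    inc <- asm$contigs
    if (nrow(inc) > 0) inc$iteration <- t
    der <- dereplicate(C, inc, config$derep_min_identity,
                       config$derep_max_edits, config)
    C <- der$contigs
    novel <- der$novel_count
    u_before <- nrow(U)
    # pairs in U are already unmapped against the previous representatives
    # (which dereplication never edits), so only this iteration's novel
    # representatives can newly explain them
    novel_reps <- C[C$novel, , drop = FALSE]
    if (nrow(novel_reps) > 0 && nrow(U) > 0) {
      mp <- map_reads(U, novel_reps, config, stats = FALSE)
      U <- split_unmapped(U, mp)
    }
    reason <- "none"
    if (pending_extra) reason <- "low_novelty_final_done"
    else if (nrow(U) < n) reason <- "pool_exhausted"
    else if (nrow(C) > 0 &&
             novel < config$novel_fraction_threshold * nrow(C))
      reason <- "pending_extra"
    else if (t >= config$max_iterations) reason <- "max_iterations"
    trace[[t]] <- tibble(
      iteration = t, seed_used = seed_t,
      subsample_size_used = nrow(S),
      assembled_contigs = nrow(inc), contig_count = nrow(C),
      novel_count = novel, unmapped_before = u_before,
      unmapped_count = nrow(U),
      termination_reason = if (reason == "pending_extra") "none" else reason)
    if (verbose)
      message(sprintf(
        "iteration %d: seed %d, subsampled %d, assembled %d, |C| %d (novel %d), |U| %d -> %d%s",
        t, seed_t, nrow(S), nrow(inc), nrow(C), novel, u_before, nrow(U),
        if (reason %in% c("none", "pending_extra")) ""
        else paste0(" [", reason, "]")))
    if (reason == "pending_extra") { pending_extra <- TRUE; next }
    if (reason != "none") break
  }
  out(C, U, bind_rows(trace))
}

#' Run the full reconstruction pipeline
#'
#' [run_iterations()] followed by post-processing: the pooled raw reads are
#' mapped to the final contig set to compute the coverage filters
#' ([filter_contigs()]), then each sample's raw reads are re-mapped to the
#' kept contigs to build the relative-abundance table
#' ([estimate_abundance()]).
#'
#' @inheritParams run_iterations
#' @param outdir Optional output directory; when given, the kept/dropped
#'   FASTA files, the abundance TSV, the filter report and the iteration
#'   trace are written there.
#' @return A `riboloop_result` object: `run`, `kept`, `dropped`,
#'   `filter_report`, `abundance`, `pooled_stats`, `per_sample_mappings`.
#' @export
run_pipeline <- function(all_reads, reference_db,
                         config = default_config(), outdir = NULL,
                         verbose = FALSE) {
  run <- run_iterations(all_reads, reference_db, config, verbose)
  empty_ab <- structure(tibble(contig_id = character()),
                        class = c("riboloop_abundance", class(tibble())))
  if (nrow(run$contigs) == 0 || nrow(all_reads) == 0) {
    res <- structure(list(run = run, kept = run$contigs,
                          dropped = run$contigs[0, ],
                          filter_report = NULL, abundance = empty_ab,
                          pooled_stats = NULL, per_sample_mappings = list()),
                     class = "riboloop_result")
    if (!is.null(outdir)) write_result(res, outdir)
    return(res)
  }
  pooled <- map_reads(all_reads, run$contigs, config)
  filt <- filter_contigs(run$contigs, pooled$per_contig,
                         config$filter_min_coverage,
                         config$filter_min_covered_fraction)
  per_sample <- list()
  ab <- empty_ab
  if (nrow(filt$kept) > 0) {
    for (s in unique(all_reads$sample)) {
      p <- all_reads[all_reads$sample == s, , drop = FALSE]
      per_sample[[s]] <- map_reads(p, filt$kept, config)
    }
    ab <- estimate_abundance(per_sample, filt$kept)
  }
  res <- structure(list(run = run, kept = filt$kept, dropped = filt$dropped,
                        filter_report = filt$report, abundance = ab,
                        pooled_stats = pooled$per_contig,
                        per_sample_mappings = per_sample),
                   class = "riboloop_result")
  if (!is.null(outdir)) write_result(res, outdir)
  res
}

write_result <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_outputs(res$kept, res$abundance, outdir,
                dropped = res$dropped, report = res$filter_report)
  readr::write_tsv(res$run$trace, file.path(outdir, "trace.tsv"))
  if (nrow(res$run$contigs) > 0)
    readr::write_tsv(res$run$contigs[, c("id", "length", "iteration",
                                         "original_id")],
                     file.path(outdir, "provenance.tsv"))
  invisible(outdir)
}
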