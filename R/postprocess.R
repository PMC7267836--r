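# Post-processing: contig quality filtering and the contig-by-sample
# relative-abundance ("OTU") table.

#' Filter low-quality contigs by coverage statistics
#'
#' A contig is kept iff its mean coverage is at least `min_cov` AND its
#' covered fraction is at least `min_covered` (values exactly at a
#' threshold are kept; "below threshold" drops). Statistics should come
#' from mapping the pooled raw reads of all samples against the contig
#' set; a contig absent from `stats` counts as zero coverage and is
#' dropped.
#'
#' @param contigs Contig tibble (`id`, `seq`, ...).
#' @param stats Per-contig statistics (the `per_contig` table of a
#'   [map_reads()] result, or a data frame with `contig_id`,
#'   `mean_coverage`, `covered_fraction`).
#' @param min_cov Minimum mean coverage (default 2).
#' @param min_covered Minimum covered fraction (default 0.80).
#' @return A list with `kept`, `dropped` (both contig tibbles) and
#'   `report` (contig, mean_coverage, covered_fraction, kept, reason).
#' @export
filter_contigs <- function(contigs, stats, min_cov = 2, min_covered = 0.8) {
  if (inherits(stats, "riboloop_mapping")) stats <- stats$per_contig
  stopifnot(all(c("contig_id", "mean_coverage", "covered_fraction")
                %in% names(stats)))
  i <- match(contigs$id, stats$contig_id)
  cov <- ifelse(is.na(i), 0, stats$mean_coverage[i])
  cfr <- ifelse(is.na(i), 0, stats$covered_fraction[i])
  keep <- cov >= min_cov & cfr >= min_covered
  reason <- dplyr::case_when(
    keep ~ "kept",
    cov < min_cov & cfr < min_covered ~ "low_coverage;low_covered_fraction",
    cov < min_cov ~ "low_coverage",
    TRUE ~ "low_covered_fraction")
  list(kept = contigs[keep, , drop = FALSE],
       dropped = contigs[!keep, , drop = FALSE],
       report = tibble(contig_id = contigs$id, mean_coverage = cov,
                       covered_fraction = cfr, kept = keep,
                       reason = reason))
}

#' Estimate per-sample relative contig abundance
#'
#' The relative abundance of a contig in a sample is
#' `(unambig_reads + ambig_read_mass) / total_reads`, from mapping that
#' sample's raw reads against the kept contigs. Because ambiguous fragment
#' mass is split 1/k across tied contigs, each sample column sums exactly
#' to the sample's mapping rate. Rows are ordered by descending pooled
#' abundance (row sum), ties by contig id.
#'
#' @param per_sample_mappings Named list of [map_reads()] results, one per
#'   sample (names are the sample labels; unnamed lists use each mapping's
#'   own sample label).
#' @param kept Contig tibble the mappings were computed against.
#' @return A `riboloop_abundance` tibble: `contig_id` plus one numeric
#'   column per sample; attribute `mapping_rates` carries the per-sample
#'   rates.
#' @export
estimate_abundance <- function(per_sample_mappings, kept) {
  stopifnot(length(per_sample_mappings) > 0)
  cols <- list(contig_id = kept$id)
  rates <- numeric(0)
  for (i in seq_along(per_sample_mappings)) {
    m <- per_sample_mappings[[i]]
    stopifnot(inherits(m, "riboloop_mapping"))
    lab <- names(per_sample_mappings)[i]
    if (is.null(lab) || !nzchar(lab)) lab <- m$per_sample$sample[1]
    if (nrow(m$per_sample) == 0 || any(m$per_sample$total_reads == 0))
      stop("sample with zero reads: ", lab)
    if (!identical(m$contig_ids, kept$id))
      stop("mapping for sample ", lab,
           " was not computed against the kept contigs")
    pc <- m$per_contig[match(kept$id, m$per_contig$contig_id), ]
    total <- sum(m$per_sample$total_reads)
    cols[[lab]] <- (pc$unambig_reads + pc$ambig_read_mass) / total
    rates[lab] <- sum(m$per_sample$mapped_reads) / total
  }
  out <- as_tibble(cols)
  pooled <- rowSums(as.matrix(out[, -1, drop = FALSE]))
  out <- out[order(-pooled, out$contig_id), ]
  attr(out, "mapping_rates") <- rates
  class(out) <- c("riboloop_abundance", class(tibble()))
  out
}

#' Write pipeline outputs
#'
#' Writes the kept contigs as single-line FASTA and the abundance matrix
#' as TSV (rows: contigs in the table's order; columns: samples), plus
#' optionally the dropped contigs and the filter report.
#'
#' @param kept Contig tibble.
#' @param table A `riboloop_abundance` tibble.
#' @param outdir Output directory (created if needed).
#' @param dropped Optional dropped-contig tibble (written as
#'   `dropped.fasta`).
#' @param report Optional filter report (written as `filter_report.tsv`).
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(kept, table, outdir, dropped = NULL,
                          report = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_fasta(kept, file.path(outdir, "contigs.filtered.fasta")),
    {
      p <- file.path(outdir, "abundance.tsv")
      readr::write_tsv(as_tibble(as.data.frame(unclass(table),
                                               check.names = FALSE)), p)
      p
    })
  if (!is.null(dropped))
    paths <- c(paths, write_fasta(dropped, file.path(outdir,
                                                     "dropped.fasta")))
  if (!is.null(report)) {
    p <- file.path(outdir, "filter_report.tsv")
    readr::write_tsv(report, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
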