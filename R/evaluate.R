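# Evaluation against ground truth: closest-match similarity in both
# directions, precision/sensitivity/F1 threshold sweeps, and abundance
# correlation.

#' Closest-match tables between contigs and sources
#'
#' Computes global pairwise identities between every reconstructed contig
#' and every ground-truth source, and reports for each contig its
#' best-matching source and for each source its best-matching contig.
#' Matches below `min_identity` are recorded as "no hit" (`NA`).
#'
#' @param contigs Contig tibble (`id`, `seq`).
#' @param sources Source tibble (`id`/`source_id`, `seq`).
#' @param min_identity Minimum identity to report a match (default 0.90).
#' @param band Alignment band half-width (see [align_global()]).
#' @return A `riboloop_matches` list: `per_contig` (contig_id, source_id,
#'   identity), `per_source` (source_id, contig_id, identity),
#'   `min_identity`.
#' @export
closest_matches <- function(contigs, sources, min_identity = 0.90,
                            band = 64) {
  if ("source_id" %in% names(sources) && !"id" %in% names(sources))
    sources <- rename(sources, id = "source_id")
  stopifnot(all(c("id", "seq") %in% names(contigs)),
            all(c("id", "seq") %in% names(sources)))
  if (nrow(contigs) == 0 || nrow(sources) == 0)
    stop("closest_matches requires non-empty contig and source sets")
  nc <- nrow(contigs); ns <- nrow(sources)
  idm <- matrix(0, nc, ns)
  for (i in seq_len(nc)) {
    for (j in seq_len(ns)) {
      b <- abs(nchar(contigs$seq[i]) - nchar(sources$seq[j])) + band
      r <- cpp_align_global(contigs$seq[i], sources$seq[j], 1, -1, -2,
                            as.integer(b))
      idm[i, j] <- identity_of(r$matches, r$mismatches, r$indels)
    }
  }
  bestc <- apply(idm, 1, which.max)
  bests <- apply(idm, 2, which.max)
  cbest <- idm[cbind(seq_len(nc), bestc)]
  sbest <- idm[cbind(bests, seq_len(ns))]
  per_contig <- tibble(
    contig_id = contigs$id,
    source_id = ifelse(cbest >= min_identity, sources$id[bestc],
                       NA_character_),
    identity = ifelse(cbest >= min_identity, cbest, NA_real_))
  per_source <- tibble(
    source_id = sources$id,
    contig_id = ifelse(sbest >= min_identity, contigs$id[bests],
                       NA_character_),
    identity = ifelse(sbest >= min_identity, sbest, NA_real_))
  structure(list(per_contig = per_contig, per_source = per_source,
                 min_identity = min_identity),
            class = "riboloop_matches")
}

#' Confusion counts at a similarity threshold
#'
#' TP: contigs whose best source similarity reaches the threshold. FP: the
#' remaining contigs, including those with no >= `min_identity` hit at
#' all. FN: sources with no contig at the threshold. Precision =
#' TP/(TP+FP); sensitivity counts sources recovered at the threshold over
#' all sources; F1 is their harmonic mean (0 when undefined).
#'
#' @param matches A [closest_matches()] result.
#' @param threshold Similarity threshold (at least the matches'
#'   `min_identity`).
#' @return A one-row tibble: threshold, tp, fp, fn, precision,
#'   sensitivity, f1.
#' @export
confusion_at <- function(matches, threshold) {
  stopifnot(inherits(matches, "riboloop_matches"))
  if (threshold < matches$min_identity)
    stop("threshold below the matches' min_identity")
  csim <- matches$per_contig$identity
  ssim <- matches$per_source$identity
  tp <- sum(!is.na(csim) & csim >= threshold)
  fp <- nrow(matches$per_contig) - tp
  tp_src <- sum(!is.na(ssim) & ssim >= threshold)
  fn <- nrow(matches$per_source) - tp_src
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  sensitivity <- if (tp_src + fn > 0) tp_src / (tp_src + fn) else 0
  f1 <- if (precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else 0
  tibble(threshold = threshold, tp = tp, fp = fp, fn = fn,
         precision = precision, sensitivity = sensitivity, f1 = f1)
}

#' Precision/sensitivity/F1 across similarity thresholds
#'
#' @param matches A [closest_matches()] result.
#' @param thresholds Numeric vector of thresholds (default 0.90 to 1.00 by
#'   0.01).
#' @return A tibble with one row per threshold (see [confusion_at()]).
#' @export
threshold_sweep <- function(matches, thresholds = seq(0.90, 1.00, by = 0.01)) {
  purrr::map_dfr(thresholds, function(t) confusion_at(matches, t))
}

#' Correlation between true and estimated abundances
#'
#' For each source with a matched contig, pairs its true relative
#' abundance with the closest contig's estimated abundance (the
#' single-sample column, or the mean across sample columns), annotated
#' with the match similarity, and computes Pearson's r on the raw values
#' plus, as an auxiliary view, on log10 values.
#'
#' @param profile Community profile (`source_id`, `abundance`).
#' @param table A `riboloop_abundance` tibble.
#' @param matches A [closest_matches()] result for the same contigs and
#'   sources.
#' @return A `riboloop_abcor` list: `pairs` (source_id, contig_id, src_ab,
#'   est_ab, sim), `pearson_r`, `pearson_r_log`, `n`.
#' @export
abundance_correlation <- function(profile, table, matches) {
  stopifnot(inherits(matches, "riboloop_matches"),
            all(c("source_id", "abundance") %in% names(profile)))
  ps <- filter(matches$per_source, !is.na(.data$contig_id))
  est_cols <- setdiff(names(table), "contig_id")
  est <- rowMeans(as.matrix(table[, est_cols, drop = FALSE]))
  names(est) <- table$contig_id
  pairs <- tibble(
    source_id = ps$source_id,
    contig_id = ps$contig_id,
    src_ab = profile$abundance[match(ps$source_id, profile$source_id)],
    est_ab = unname(est[ps$contig_id]),
    sim = ps$identity)
  pairs <- filter(pairs, !is.na(.data$est_ab))
  if (nrow(pairs) < 3)
    stop("abundance correlation undefined: fewer than 3 matched pairs")
  r <- cor(pairs$src_ab, pairs$est_ab)
  r_log <- cor(log10(pmax(pairs$src_ab, 1e-12)),
               log10(pmax(pairs$est_ab, 1e-12)))
  structure(list(pairs = pairs, pearson_r = r, pearson_r_log = r_log,
                 n = nrow(pairs)),
            class = "riboloop_abcor")
}

#' Evaluate a reconstruction against ground truth
#'
#' Convenience wrapper: closest matches, the full threshold sweep, and
#' (when an abundance table is supplied) the abundance correlation.
#'
#' @param contigs Contig tibble (`id`, `seq`).
#' @param profile Community profile (`source_id`, `seq`, `abundance`).
#' @param abundance Optional `riboloop_abundance` tibble.
#' @param min_identity Minimum match identity (default 0.90).
#' @param thresholds Sweep thresholds.
#' @return A `riboloop_eval` list: `matches`, `sweep`, `abundance_cor`
#'   (NULL when not computed).
#' @export
evaluate_contigs <- function(contigs, profile, abundance = NULL,
                             min_identity = 0.90,
                             thresholds = seq(0.90, 1.00, by = 0.01)) {
  matches <- closest_matches(contigs,
                             tibble(id = profile$source_id,
                                    seq = profile$seq),
                             min_identity)
  sweep <- threshold_sweep(matches, thresholds)
  ac <- NULL
  if (!is.null(abundance) && nrow(abundance) > 0)
    ac <- tryCatch(abundance_correlation(profile, abundance, matches),
                   error = function(e) NULL)
  structure(list(matches = matches, sweep = sweep, abundance_cor = ac),
            class = "riboloop_eval")
}
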