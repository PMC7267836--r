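# Reference-guided EM assembler.
#
# Candidates are reference sequences that attract seeded read hits; the EM
# alternates read-to-candidate posteriors (E) with prior re-estimation and
# posterior-weighted consensus polishing (M), pruning candidates whose prior
# collapses and merging candidate pairs above the mutual-identity ceiling.
# The read likelihood uses the best glocal alignment of a read unit to each
# candidate: P(r|j) = (1-eps)^matches * (eps/3)^mismatches.
#
# Internals are vectorised over the (read unit x candidate) hit table; the
# posterior vector `z` is kept aligned row-by-row with `hits` between the
# E- and M-step of one EM iteration.

em_params <- function(config) {
  list(k = as.integer(config$seed_k), minhits = as.integer(config$map_minhits),
       maxindel = as.integer(config$map_maxindel),
       min_identity = config$em_min_identity,
       match = config$align_match, mismatch = config$align_mismatch,
       gap = config$align_gap)
}

em_map_hits <- function(unit_seqs, cand_ids, cand_seqs, p) {
  h <- cpp_map_reads(unit_seqs, cand_seqs, p$k, p$minhits, p$maxindel,
                     p$min_identity, p$match, p$mismatch, p$gap, TRUE,
                     0L, 0)
  tibble(unit_idx = h$query, cand = cand_ids[h$target], score = h$score,
         identity = h$identity, matches = h$matches,
         mismatches = h$mismatches, indels = h$indels,
         tstart = h$tstart, strand = h$strand)
}

#' Initialise the EM candidate model
#'
#' Candidates are the reference sequences receiving at least one seeded,
#' identity-qualified read alignment; priors start uniform over candidates.
#'
#' @param units Read units (from [pair_units()]); merged reads and unmerged
#'   mates are independent observations.
#' @param reference_db Reference tibble with columns `id`, `seq`.
#' @param config A [default_config()] object (uses `seed_k`, `map_minhits`,
#'   `map_maxindel`, `em_min_identity` and the alignment scores).
#' @return A `riboloop_em` model (zero candidates signals that no assembly
#'   is possible).
#' @export
em_initialize <- function(units, reference_db, config = default_config()) {
  stopifnot(all(c("id", "seq") %in% names(reference_db)))
  p <- em_params(config)
  empty <- structure(
    list(candidates = tibble(id = character(), seq = character(),
                             prior = numeric()),
         hits = NULL, z = NULL, posteriors = NULL, retained = integer(),
         stale = character(), unit_rc = character(), em_iteration = 0L,
         params = p),
    class = "riboloop_em")
  if (is.null(units) || nrow(units) == 0 || nrow(reference_db) == 0)
    return(empty)
  hits <- em_map_hits(units$seq, reference_db$id, reference_db$seq, p)
  cand_ids <- sort(unique(hits$cand))
  if (length(cand_ids) == 0) return(empty)
  keep <- reference_db[match(cand_ids, reference_db$id), ]
  structure(
    list(candidates = tibble(id = keep$id, seq = keep$seq,
                             prior = rep(1 / nrow(keep), nrow(keep))),
         hits = hits, z = NULL, posteriors = NULL,
         retained = seq_len(nrow(units)),
         stale = character(), unit_rc = cpp_revcomp(units$seq),
         em_iteration = 0L, params = p),
    class = "riboloop_em")
}

# Re-score cached alignments against candidates whose consensus changed.
# The read-candidate graph is fixed at initialisation; consensus updates
# (substitution-only, coordinate-stable) re-score each cached hit at its
# recorded position.  Hits falling below the identity floor are dropped.
em_refresh_hits <- function(model, units) {
  if (length(model$stale) == 0 || length(model$retained) == 0) return(model)
  stale <- intersect(model$stale, model$candidates$id)
  h <- model$hits
  rows <- which(h$cand %in% stale)
  if (length(rows)) {
    p <- model$params
    ci <- match(h$cand[rows], model$candidates$id)
    oriented <- ifelse(h$strand[rows] > 0, units$seq[h$unit_idx[rows]],
                       model$unit_rc[h$unit_idx[rows]])
    rs <- cpp_rescore_hits(oriented, model$candidates$seq,
                           as.integer(ci), h$tstart[rows], h$indels[rows],
                           p$maxindel, p$match, p$mismatch, p$gap)
    h$matches[rows] <- rs$matches
    h$mismatches[rows] <- rs$mismatches
    h$indels[rows] <- rs$indels
    h$tstart[rows] <- rs$tstart
    h$score[rows] <- rs$score
    h$identity[rows] <- rs$identity
    model$hits <- h[h$identity >= p$min_identity, ]
  }
  model$z <- NULL
  model$stale <- character()
  model
}

em_empty_posteriors <- function(model) {
  model$posteriors <- tibble(unit_idx = integer(), cand = character(),
                             z = numeric())
  model$z <- NULL
  model$retained <- integer()
  model
}

#' EM E-step: read-to-candidate posteriors
#'
#' Computes `z_rj` proportional to `prior_j * (1-eps)^matches *
#' (eps/3)^mismatches` from each retained read unit's best alignment to
#' candidate `j`, normalised over candidates. Units with no qualifying
#' alignment (or zero total weight) are dropped from the model and never
#' re-added.
#'
#' @param model A `riboloop_em` model.
#' @param units The read-unit table the model was initialised with.
#' @param epsilon Per-base error rate, in (0, 0.75).
#' @return The model with updated `posteriors` and `retained`.
#' @export
em_e_step <- function(model, units, epsilon = 0.005) {
  stopifnot(inherits(model, "riboloop_em"))
  if (epsilon <= 0 || epsilon >= 0.75) stop("epsilon must be in (0, 0.75)")
  if (nrow(model$candidates) == 0 || length(model$retained) == 0)
    return(em_empty_posteriors(model))
  model <- em_refresh_hits(model, units)
  nu <- nrow(units)
  ret <- logical(nu)
  ret[model$retained] <- TRUE
  h <- model$hits[ret[model$hits$unit_idx], ]
  if (nrow(h) == 0) return(em_empty_posteriors(model))
  pri <- stats::setNames(model$candidates$prior, model$candidates$id)
  p <- unname(pri[h$cand])
  w <- p * exp(h$matches * log1p(-epsilon) + h$mismatches * log(epsilon / 3))
  w[is.na(w)] <- 0
  tot_by_unit <- numeric(nu)
  nz <- which(w > 0)
  if (length(nz)) {
    agg <- rowsum(w[nz], h$unit_idx[nz])
    tot_by_unit[as.integer(rownames(agg))] <- agg[, 1]
  }
  z <- numeric(nrow(h))
  ok <- w > 0
  z[ok] <- w[ok] / tot_by_unit[h$unit_idx[ok]]
  model$hits <- h
  model$z <- z
  model$posteriors <- tibble(unit_idx = h$unit_idx[ok], cand = h$cand[ok],
                             z = z[ok])
  model$retained <- which(ret & tot_by_unit > 0)
  model
}

consensus_seq <- function(seq, counts) {
  L <- nchar(seq)
  cur <- strsplit(seq, "")[[1]]
  curidx <- match(cur, DNA_BASES)
  maxv <- pmax(counts[1, ], counts[2, ], counts[3, ], counts[4, ])
  curv <- ifelse(is.na(curidx), -1, counts[cbind(curidx, seq_len(L))])
  argmax <- max.col(t(counts), ties.method = "first")
  new <- ifelse(maxv <= 0 | curv >= maxv, cur, DNA_BASES[argmax])
  paste(new, collapse = "")
}

#' EM M-step: priors, consensus polishing, pruning
#'
#' Priors become the normalised posterior mass per candidate; each
#' candidate's consensus is re-called per position as the posterior-weighted
#' majority base over its aligned reads (ties keep the current base;
#' positions without aligned mass are untouched); candidates with prior
#' below `config$em_prune_prior` are removed and priors renormalised.
#'
#' @inheritParams em_e_step
#' @param config A [default_config()] object.
#' @return The model with updated `candidates` (zero candidates if all were
#'   pruned).
#' @export
em_m_step <- function(model, units, config = default_config()) {
  stopifnot(inherits(model, "riboloop_em"))
  h <- model$hits
  z <- model$z
  if (is.null(z) || length(z) == 0 || sum(z) == 0) {
    model$candidates <- model$candidates[0, ]
    return(model)
  }
  ci <- match(h$cand, model$candidates$id)
  mass <- rowsum(z, ci)
  pri <- numeric(nrow(model$candidates))
  pri[as.integer(rownames(mass))] <- mass[, 1]
  model$candidates$prior <- pri / sum(pri)
  # consensus polishing per candidate
  p <- model$params
  groups <- split(seq_along(ci), ci)
  for (g in names(groups)) {
    cidx <- as.integer(g)
    rows <- groups[[g]]
    rows <- rows[z[rows] > 1e-12]
    if (length(rows) == 0) next
    oriented <- ifelse(h$strand[rows] > 0, units$seq[h$unit_idx[rows]],
                       model$unit_rc[h$unit_idx[rows]])
    counts <- cpp_consensus_counts(model$candidates$seq[cidx], oriented,
                                   h$tstart[rows], h$indels[rows], z[rows],
                                   p$maxindel, p$match, p$mismatch, p$gap)
    new <- consensus_seq(model$candidates$seq[cidx], counts)
    if (new != model$candidates$seq[cidx]) {
      model$candidates$seq[cidx] <- new
      model$stale <- union(model$stale, model$candidates$id[cidx])
    }
  }
  # prune collapsed candidates
  keep <- model$candidates$prior >= config$em_prune_prior
  model$candidates <- model$candidates[keep, ]
  if (nrow(model$candidates) == 0) return(model)
  model$candidates$prior <-
    model$candidates$prior / sum(model$candidates$prior)
  keep_row <- model$hits$cand %in% model$candidates$id
  model$hits <- model$hits[keep_row, ]
  model$z <- NULL
  model$stale <- intersect(model$stale, model$candidates$id)
  model$em_iteration <- model$em_iteration + 1L
  model
}

#' Merge near-identical EM candidates
#'
#' While any candidate pair has global identity at or above
#' `merge_identity`, the pair is merged into the higher-prior candidate
#' (ties: longer, then lexicographically smaller id), summing priors. This
#' enforces the assembler's resolution ceiling: sequence variants above the
#' ceiling are not reported separately.
#'
#' @inheritParams em_e_step
#' @param merge_identity Mutual-identity ceiling (default 0.97).
#' @return The model with merged candidates.
#' @export
em_merge_similar <- function(model, merge_identity = 0.97) {
  stopifnot(inherits(model, "riboloop_em"))
  cand <- model$candidates
  if (nrow(cand) < 2) return(model)
  ord <- order(-cand$prior, -nchar(cand$seq), cand$id)
  cand <- cand[ord, ]
  idm <- pairwise_identity(cand$seq, merge_identity, k = model$params$k)
  reps <- integer(0)
  absorbed_into <- rep(NA_integer_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    hit <- reps[idm[reps, i] >= merge_identity]
    if (length(hit)) absorbed_into[i] <- hit[1] else reps <- c(reps, i)
  }
  for (i in which(!is.na(absorbed_into)))
    cand$prior[absorbed_into[i]] <- cand$prior[absorbed_into[i]] +
      cand$prior[i]
  merged <- cand[is.na(absorbed_into), ]
  gone <- cand$id[!is.na(absorbed_into)]
  model$candidates <- merged
  if (length(gone)) {
    model$hits <- model$hits[!model$hits$cand %in% gone, ]
    model$z <- NULL
    model$stale <- setdiff(model$stale, gone)
  }
  model
}

#' Reference-guided EM assembly of a read subsample
#'
#' Runs initialisation followed by (E-step, M-step, candidate merging)
#' until `config$em_max_iterations` or until the L1 change in the prior
#' vector falls below `config$em_tol`, then reports the consensus sequences
#' of candidates with prior at least `config$em_report_prior`.
#'
#' @param pairs Read-pair tibble (the subsample to assemble).
#' @param reference_db Reference tibble (`id`, `seq`).
#' @param config A [default_config()] object.
#' @param run_label Prefix encoding the run/iteration in contig ids.
#' @return A `riboloop_assembly` list with `contigs` (tibble `id`, `seq`,
#'   `prior`, `candidate`), `model`, and `em_iterations`. Empty inputs or a
#'   fully pruned model yield zero contigs.
#' @export
em_assemble <- function(pairs, reference_db, config = default_config(),
                        run_label = "asm1") {
  empty <- structure(list(contigs = tibble(id = character(),
                                           seq = character(),
                                           prior = numeric(),
                                           candidate = character()),
                          model = NULL, em_iterations = 0L),
                     class = "riboloop_assembly")
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  units <- pair_units(pairs, config)
  model <- em_initialize(units, reference_db, config)
  if (nrow(model$candidates) == 0) return(empty)
  iters <- 0L
  for (t in seq_len(config$em_max_iterations)) {
    pi_old <- stats::setNames(model$candidates$prior, model$candidates$id)
    model <- em_e_step(model, units, config$em_epsilon)
    model <- em_m_step(model, units, config)
    if (nrow(model$candidates) == 0) break
    model <- em_merge_similar(model, config$em_merge_identity)
    iters <- t
    pi_new <- stats::setNames(model$candidates$prior, model$candidates$id)
    ids <- union(names(pi_old), names(pi_new))
    o <- ifelse(is.na(pi_old[ids]), 0, pi_old[ids])
    n <- ifelse(is.na(pi_new[ids]), 0, pi_new[ids])
    l1 <- sum(abs(n - o))
    if (l1 < config$em_tol) break
  }
  cand <- model$candidates
  if (nrow(cand) == 0) return(empty)
  cand <- cand[cand$prior >= config$em_report_prior, ]
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(-cand$prior, cand$id), ]
  structure(list(contigs = tibble(id = sprintf("%s_%03d", run_label,
                                               seq_len(nrow(cand))),
                                  seq = cand$seq, prior = cand$prior,
                                  candidate = cand$id),
                 model = model, em_iterations = iters),
            class = "riboloop_assembly")
}
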