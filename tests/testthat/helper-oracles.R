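# Independent plain-R oracles.  These re-derive alignment, clustering and
# confusion counts from their definitions, sharing no code with the
# package's compiled kernel.

.ORACLE_BASES <- c("A", "C", "G", "T")

oracle_match <- function(x, y) {
  x %in% .ORACLE_BASES && x == y
}

# Full-matrix Needleman-Wunsch under the lexicographic objective
# (score, then matches), with preference diagonal > gap-in-b > gap-in-a on
# full ties; maximising matches among co-optimal paths makes the reported
# identity canonical (and symmetric under argument swap).
oracle_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  S <- matrix(0, m + 1, n + 1)
  MM <- matrix(0L, m + 1, n + 1)
  P <- matrix(0L, m + 1, n + 1)
  S[1, ] <- (0:n) * gap
  if (n > 0) P[1, 2:(n + 1)] <- 3L
  S[, 1] <- (0:m) * gap
  if (m > 0) P[2:(m + 1), 1] <- 2L
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      hit <- oracle_match(A[i], B[j])
      sub <- if (hit) match else mismatch
      cand <- c(S[i, j] + sub, S[i, j + 1] + gap, S[i + 1, j] + gap)
      cmat <- c(MM[i, j] + as.integer(hit), MM[i, j + 1], MM[i + 1, j])
      best <- max(cand)
      tie <- which(cand == best)
      k <- tie[which.max(cmat[tie])]  # max matches; first on full tie
      S[i + 1, j + 1] <- cand[k]
      MM[i + 1, j + 1] <- cmat[k]
      P[i + 1, j + 1] <- k
    }
  }
  i <- m + 1; j <- n + 1; mat <- mis <- ind <- 0L
  while (i > 1 || j > 1) {
    p <- P[i, j]
    if (p == 1L) {
      if (oracle_match(A[i - 1], B[j - 1])) mat <- mat + 1L
      else mis <- mis + 1L
      i <- i - 1; j <- j - 1
    } else if (p == 2L) { ind <- ind + 1L; i <- i - 1 }
    else { ind <- ind + 1L; j <- j - 1 }
  }
  list(score = S[m + 1, n + 1], matches = mat, mismatches = mis,
       indels = ind, identity = mat / (mat + mis + ind))
}

# Fitting alignment of `read` inside `target` with at most `maxindel`
# indel columns, via an (i, j, g) DP; free target prefix/suffix.  Cell
# preference diagonal > gap-in-target > gap-in-read at score ties; the end
# cell is the first maximum scanning j then g ascending (mirroring the
# documented deterministic contract).
oracle_glocal <- function(read, target, maxindel = 1,
                          match = 1, mismatch = -1, gap = -2) {
  R <- strsplit(read, "")[[1]]
  T_ <- strsplit(target, "")[[1]]
  m <- length(R); n <- length(T_); G <- maxindel
  S <- array(-Inf, c(m + 1, n + 1, G + 1))
  M <- array(0L, dim(S)); MM <- array(0L, dim(S)); IND <- array(0L, dim(S))
  ST <- array(NA_integer_, dim(S))        # start column of the alignment
  S[1, , 1] <- 0
  ST[1, , 1] <- 0:n
  for (i in seq_len(m)) {
    for (j in 0:n) {
      for (g in 0:G) {
        best <- -Inf; from <- NULL
        if (j >= 1 && is.finite(S[i, j, g + 1])) {
          sub <- if (oracle_match(R[i], T_[j])) match else mismatch
          s <- S[i, j, g + 1] + sub
          if (s > best) { best <- s; from <- c(i, j, g + 1, 1L) }
        }
        if (g >= 1 && is.finite(S[i, j + 1, g])) {
          s <- S[i, j + 1, g] + gap        # gap in target, consume read base
          if (s > best) { best <- s; from <- c(i, j + 1, g, 2L) }
        }
        if (g >= 1 && j >= 1 && is.finite(S[i + 1, j, g])) {
          s <- S[i + 1, j, g] + gap        # gap in read, consume target base
          if (s > best) { best <- s; from <- c(i + 1, j, g, 3L) }
        }
        if (!is.null(from) && best > S[i + 1, j + 1, g + 1]) {
          S[i + 1, j + 1, g + 1] <- best
          mv <- from[4]
          M[i + 1, j + 1, g + 1] <- M[from[1], from[2], from[3]] +
            as.integer(mv == 1L && oracle_match(R[i], T_[j]))
          MM[i + 1, j + 1, g + 1] <- MM[from[1], from[2], from[3]] +
            as.integer(mv == 1L && !oracle_match(R[i], T_[j]))
          IND[i + 1, j + 1, g + 1] <- IND[from[1], from[2], from[3]] +
            as.integer(mv != 1L)
          ST[i + 1, j + 1, g + 1] <- ST[from[1], from[2], from[3]]
        }
      }
    }
  }
  best <- -Inf; bj <- NA; bg <- NA
  for (j in 0:n) for (g in 0:G)
    if (S[m + 1, j + 1, g + 1] > best) {
      best <- S[m + 1, j + 1, g + 1]; bj <- j; bg <- g
    }
  if (!is.finite(best)) return(NULL)
  list(score = best, matches = M[m + 1, bj + 1, bg + 1],
       mismatches = MM[m + 1, bj + 1, bg + 1],
       indels = IND[m + 1, bj + 1, bg + 1],
       tstart = ST[m + 1, bj + 1, bg + 1], tend = bj,
       identity = M[m + 1, bj + 1, bg + 1] /
         (M[m + 1, bj + 1, bg + 1] + MM[m + 1, bj + 1, bg + 1] +
            IND[m + 1, bj + 1, bg + 1]))
}

# reverse complement without the package kernel
oracle_revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""),
           character(1)))
}

# duplicate criterion re-derived with the R oracle aligner (both strands)
oracle_is_duplicate <- function(short, long, min_identity, max_edits) {
  for (q in c(short, oracle_revcomp(short))) {
    r <- oracle_glocal(q, long, maxindel = max_edits)
    if (!is.null(r) && r$identity >= min_identity && r$indels <= max_edits)
      return(TRUE)
  }
  FALSE
}

# greedy longest-first clustering from its definition: sort by length desc
# (earlier iteration, then id, on ties), absorb into the first accepted
# representative meeting the duplicate criterion
oracle_dereplicate <- function(seqs, ids, iterations, min_identity,
                               max_edits) {
  iter_key <- ifelse(is.na(iterations), .Machine$integer.max, iterations)
  ord <- order(-nchar(seqs), iter_key, ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  reps <- integer(0)
  for (i in seq_along(seqs)) {
    dup <- FALSE
    for (r in reps) {
      if (oracle_is_duplicate(seqs[i], seqs[r], min_identity, max_edits)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) reps <- c(reps, i)
  }
  ids[reps]
}

# direct recount of confusion measures from the two best-hit tables
oracle_confusion <- function(contig_sims, source_sims, threshold) {
  tp <- 0L
  for (s in contig_sims) if (!is.na(s) && s >= threshold) tp <- tp + 1L
  fp <- length(contig_sims) - tp
  tps <- 0L
  for (s in source_sims) if (!is.na(s) && s >= threshold) tps <- tps + 1L
  fn <- length(source_sims) - tps
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tps + fn > 0) tps / (tps + fn) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, sensitivity = sens,
       f1 = f1)
}
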