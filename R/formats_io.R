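# FASTA/FASTQ input-output and read-pair overlap merging.

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated and uppercased. Record ids are the
#' first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(tibble(id = character(), seq = character()))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stop("malformed FASTA: line 1 does not start with '>' in ", path)
  rec <- cumsum(is_hdr)
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    bad <- which(is_hdr)[!nzchar(ids)][1]
    stop("malformed FASTA: empty header at line ", bad, " in ", path)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    bad <- which(is_hdr)[ids == dup][2]
    stop("malformed FASTA: duplicate id '", dup, "' at line ", bad, " in ", path)
  }
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 paste, collapse = "", FUN.VALUE = character(1))
  out <- character(length(ids))
  got <- as.integer(names(seqs))
  out[got] <- toupper(seqs)
  if (any(!nzchar(out))) {
    miss <- which(!nzchar(out))[1]
    stop("malformed FASTA: empty sequence for record '", ids[miss],
         "' (header line ", which(is_hdr)[miss], ") in ", path)
  }
  tibble(id = ids, seq = unname(out))
}

#' Write sequences to FASTA
#'
#' @param x A data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for wrapping; `0` (default) writes single-line
#'   sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 0) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(x) == 0) return(invisible(path))
  body <- if (width > 0) {
    vapply(x$seq, function(s) {
      starts <- seq(1, nchar(s), by = width)
      paste(substring(s, starts, pmin(starts + width - 1, nchar(s))),
            collapse = "\n")
    }, character(1))
  } else x$seq
  writeLines(paste0(">", x$id, "\n", body), con)
  invisible(path)
}

read_fastq_one <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  n <- length(lines) / 4
  if (n == 0) return(tibble(id = character(), seq = character(),
                            qual = character()))
  at <- lines[seq(1, length(lines), by = 4)]
  if (any(!startsWith(at, "@")))
    stop("malformed FASTQ (record does not start with '@'): ", path)
  id <- sub("\\s.*$", "", sub("^@", "", at))
  id <- sub("/[12]$", "", id)
  tibble(id = id,
         seq = toupper(lines[seq(2, length(lines), by = 4)]),
         qual = lines[seq(4, length(lines), by = 4)])
}

#' Read paired FASTQ files
#'
#' Mates are matched by record order; a sample label is attached to every
#' pair. Files must contain the same number of 4-line records, and each
#' record's quality string must match its sequence length.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @param sample Sample label attached to every pair.
#' @return A read-pair tibble with columns `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `sample`.
#' @export
read_fastq_pairs <- function(path1, path2, sample) {
  r1 <- read_fastq_one(path1)
  r2 <- read_fastq_one(path2)
  if (nrow(r1) != nrow(r2))
    stop("paired FASTQ files differ in record count: ",
         nrow(r1), " vs ", nrow(r2))
  bad <- which(nchar(r1$seq) != nchar(r1$qual) |
               nchar(r2$seq) != nchar(r2$qual))
  if (length(bad))
    stop("FASTQ record ", bad[1], ": sequence/quality length mismatch")
  tibble(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
         seq2 = r2$seq, qual2 = r2$qual, sample = sample)
}

#' Write paired FASTQ files
#'
#' @param pairs A read-pair tibble (see [read_fastq_pairs()]).
#' @param path1,path2 Output FASTQ paths for mate 1 and mate 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  writeLines(paste0("@", pairs$id, "/1\n", pairs$seq1, "\n+\n", pairs$qual1),
             path1)
  writeLines(paste0("@", pairs$id, "/2\n", pairs$seq2, "\n+\n", pairs$qual2),
             path2)
  invisible(c(path1, path2))
}

validate_pairs <- function(pairs) {
  need <- c("id", "seq1", "qual1", "seq2", "qual2", "sample")
  if (!all(need %in% names(pairs)))
    stop("read-pair table must have columns ", paste(need, collapse = ", "))
  invisible(pairs)
}

#' Merge overlapping read pairs
#'
#' For each pair, the reverse complement of mate 2 is slid along the 3' end
#' of mate 1; the best-scoring overlap of at least `min_overlap` bases with
#' a mismatch rate at most `max_mismatch_rate` merges the pair into one
#' sequence (overlap bases resolved by the higher quality score, ties keep
#' the mate-1 base). Pairs with no qualifying overlap are kept as pairs.
#'
#' @param pairs A read-pair tibble.
#' @param min_overlap Minimum overlap length in bases.
#' @param max_mismatch_rate Maximum fraction of mismatching bases in the
#'   overlap.
#' @return The input with columns `merged` (logical), `mseq`, `mqual`
#'   (merged sequence/quality, `NA` where unmerged).
#' @export
#' @examples
#' p <- tibble::tibble(id = "r1", seq1 = "ACGTACGT",
#'                     qual1 = strrep("?", 8),
#'                     seq2 = revcomp("TACGTGGG"), qual2 = strrep("?", 8),
#'                     sample = "S1")
#' merge_pairs(p, min_overlap = 5)$mseq
merge_pairs <- function(pairs, min_overlap = 20, max_mismatch_rate = 0.05) {
  validate_pairs(pairs)
  if (nrow(pairs) == 0)
    return(mutate(pairs, merged = logical(0), mseq = character(0),
                  mqual = character(0)))
  res <- cpp_merge_pairs(pairs$seq1, pairs$seq2, pairs$qual1, pairs$qual2,
                         as.integer(min_overlap), max_mismatch_rate)
  mutate(pairs, merged = res$merged, mseq = res$seq, mqual = res$qual)
}

#' Explode read pairs into mapping/assembly units
#'
#' Pairs that merge (see [merge_pairs()]) become one single-sequence unit
#' (`mate = 0`); pairs that do not merge contribute their two mates as
#' separate units (`mate = 1`, `mate = 2`). Units are the observations the
#' mapper and the EM assembler operate on.
#'
#' @param pairs Read-pair tibble.
#' @param config A [default_config()] object (uses the `merge_*` fields).
#' @return A tibble with columns `pair_idx`, `pair_id`, `sample`, `mate`,
#'   `seq`, `qual`, `unit`.
#' @export
pair_units <- function(pairs, config = default_config()) {
  validate_pairs(pairs)
  m <- merge_pairs(pairs, config$merge_min_overlap,
                   config$merge_max_mismatch_rate)
  m$pair_idx <- seq_len(nrow(m))
  mg <- filter(m, .data$merged)
  um <- filter(m, !.data$merged)
  units <- bind_rows(
    tibble(pair_idx = mg$pair_idx, pair_id = mg$id, sample = mg$sample,
           mate = 0L, seq = mg$mseq, qual = mg$mqual),
    tibble(pair_idx = um$pair_idx, pair_id = um$id, sample = um$sample,
           mate = 1L, seq = um$seq1, qual = um$qual1),
    tibble(pair_idx = um$pair_idx, pair_id = um$id, sample = um$sample,
           mate = 2L, seq = um$seq2, qual = um$qual2)
  )
  units <- arrange(units, .data$pair_idx, .data$mate)
  units$unit <- paste0(units$pair_id, "/", c("m", "1", "2")[units$mate + 1L])
  units
}
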